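"iteration","removed_id","score","products_remaining","budget_remaining"
1,"ka09",0.111111111111111,32,44
2,"ka03",1.14285714285714,24,37
3,"ka07",1,18,31
4,"ka02",1,12,25
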