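"rule","step","n_products"
"amide",1,12
"amide",2,12
"buchwald",1,20
"buchwald",2,4
"suzuki",1,1
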