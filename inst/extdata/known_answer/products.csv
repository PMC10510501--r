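"inchi","smiles","min_step"
"InChI=1S/C10H13NO/c1-2-10(12)11-8-9-6-4-3-5-7-9/h3-7H,2,8H2,1H3,(H,11,12)","CCC(=O)NCc1ccccc1",1
"InChI=1S/C10H13NO/c1-3-10(12)11(2)9-7-5-4-6-8-9/h4-8H,3H2,1-2H3","CCC(=O)N(C)c1ccccc1",2
"InChI=1S/C10H13NO/c1-3-11(9(2)12)10-7-5-4-6-8-10/h4-8H,3H2,1-2H3","CCN(C(C)=O)c1ccccc1",2
"InChI=1S/C11H15NO/c1-3-11(13)12(4-2)10-8-6-5-7-9-10/h5-9H,3-4H2,1-2H3","CCC(=O)N(CC)c1ccccc1",2
"InChI=1S/C11H15NO/c1-9(2)11(13)12-8-10-6-4-3-5-7-10/h3-7,9H,8H2,1-2H3,(H,12,13)","CC(C)C(=O)NCc1ccccc1",1
"InChI=1S/C11H15NO/c1-9(2)11(13)12(3)10-7-5-4-6-8-10/h4-9H,1-3H3","CC(C)C(=O)N(C)c1ccccc1",2
"InChI=1S/C11H15NO/c1-9(2)12(10(3)13)11-7-5-4-6-8-11/h4-9H,1-3H3","CC(=O)N(c1ccccc1)C(C)C",2
"InChI=1S/C12H10/c1-3-7-11(8-4-1)12-9-5-2-6-10-12/h1-10H","c1ccc(-c2ccccc2)cc1",1
"InChI=1S/C12H17NO/c1-4-12(14)13(10(2)3)11-8-6-5-7-9-11/h5-10H,4H2,1-3H3","CCC(=O)N(c1ccccc1)C(C)C",2
"InChI=1S/C12H17NO/c1-4-13(12(14)10(2)3)11-8-6-5-7-9-11/h5-10H,4H2,1-3H3","CCN(C(=O)C(C)C)c1ccccc1",2
"InChI=1S/C13H13N/c1-14(12-8-4-2-5-9-12)13-10-6-3-7-11-13/h2-11H,1H3","CN(c1ccccc1)c1ccccc1",2
"InChI=1S/C13H13N/c1-3-7-12(8-4-1)11-14-13-9-5-2-6-10-13/h1-10,14H,11H2","c1ccc(CNc2ccccc2)cc1",1
"InChI=1S/C13H19NO/c1-10(2)13(15)14(11(3)4)12-8-6-5-7-9-12/h5-11H,1-4H3","CC(C)C(=O)N(c1ccccc1)C(C)C",2
"InChI=1S/C14H15N/c1-2-15(13-9-5-3-6-10-13)14-11-7-4-8-12-14/h3-12H,2H2,1H3","CCN(c1ccccc1)c1ccccc1",2
"InChI=1S/C15H15NO/c1-13(17)16(15-10-6-3-7-11-15)12-14-8-4-2-5-9-14/h2-11H,12H2,1H3","CC(=O)N(Cc1ccccc1)c1ccccc1",2
"InChI=1S/C15H17N/c1-13(2)16(14-9-5-3-6-10-14)15-11-7-4-8-12-15/h3-13H,1-2H3","CC(C)N(c1ccccc1)c1ccccc1",2
"InChI=1S/C16H17NO/c1-2-16(18)17(15-11-7-4-8-12-15)13-14-9-5-3-6-10-14/h3-12H,2,13H2,1H3","CCC(=O)N(Cc1ccccc1)c1ccccc1",2
"InChI=1S/C17H19NO/c1-14(2)17(19)18(16-11-7-4-8-12-16)13-15-9-5-3-6-10-15/h3-12,14H,13H2,1-2H3","CC(C)C(=O)N(Cc1ccccc1)c1ccccc1",2
"InChI=1S/C19H17N/c1-4-10-17(11-5-1)16-20(18-12-6-2-7-13-18)19-14-8-3-9-15-19/h1-15H,16H2","c1ccc(CN(c2ccccc2)c2ccccc2)cc1",2
"InChI=1S/C3H7NO/c1-3(5)4-2/h1-2H3,(H,4,5)","CNC(C)=O",1
"InChI=1S/C4H9NO/c1-3-4(6)5-2/h3H2,1-2H3,(H,5,6)","CCC(=O)NC",1
"InChI=1S/C4H9NO/c1-3-5-4(2)6/h3H2,1-2H3,(H,5,6)","CCNC(C)=O",1
"InChI=1S/C5H11NO/c1-3-5(7)6-4-2/h3-4H2,1-2H3,(H,6,7)","CCNC(=O)CC",1
"InChI=1S/C5H11NO/c1-4(2)5(7)6-3/h4H,1-3H3,(H,6,7)","CNC(=O)C(C)C",1
"InChI=1S/C5H11NO/c1-4(2)6-5(3)7/h4H,1-3H3,(H,6,7)","CC(=O)NC(C)C",1
"InChI=1S/C6H13NO/c1-4-6(8)7-5(2)3/h5H,4H2,1-3H3,(H,7,8)","CCC(=O)NC(C)C",1
"InChI=1S/C6H13NO/c1-4-7-6(8)5(2)3/h5H,4H2,1-3H3,(H,7,8)","CCNC(=O)C(C)C",1
"InChI=1S/C7H15NO/c1-5(2)7(9)8-6(3)4/h5-6H,1-4H3,(H,8,9)","CC(C)NC(=O)C(C)C",1
"InChI=1S/C7H9N/c1-8-7-5-3-2-4-6-7/h2-6,8H,1H3","CNc1ccccc1",1
"InChI=1S/C8H11N/c1-2-9-8-6-4-3-5-7-8/h3-7,9H,2H2,1H3","CCNc1ccccc1",1
"InChI=1S/C9H11NO/c1-8(11)10-7-9-5-3-2-4-6-9/h2-6H,7H2,1H3,(H,10,11)","CC(=O)NCc1ccccc1",1
"InChI=1S/C9H11NO/c1-8(11)10(2)9-6-4-3-5-7-9/h3-7H,1-2H3","CC(=O)N(C)c1ccccc1",2
"InChI=1S/C9H13N/c1-8(2)10-9-6-4-3-5-7-9/h3-8,10H,1-2H3","CC(C)Nc1ccccc1",1
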