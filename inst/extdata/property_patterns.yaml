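# SMARTS pattern lists backing the group-count descriptors.
# Acidic: carboxylic, sulfonic, phosphonic acids and N-H tetrazole.
# Basic: aliphatic amines (not amide/sulfonamide/aniline nitrogens),
# amidines and guanidines.
acidic:
  carboxylic_acid: "[CX3](=[OX1])[OX2H1]"
  sulfonic_acid: "[SX4](=[OX1])(=[OX1])[OX2H1]"
  phosphonic_acid: "[PX4](=[OX1])([OX2H1])"
  tetrazole: "c1nnn[nH]1"
basic:
  aliphatic_amine: "[NX3;!$([NX3][CX3]=[OX1]);!$([NX3][CX3]=[SX1]);!$([NX3][CX3]=[NX2]);!$([NX3][SX4](=[OX1])=[OX1]);!$([NX3]=*);!$([N+]);!$([NX3][a]);!$([NX3][OX2]);!$([NX3][NX3]);$([NX3][CX4])]"
  amidine: "[NX3][CX3;!$([CX3]([NX3])[NX3])]=[NX2;!$([NX2][CX3]=[OX1])]"
  guanidine: "[NX3][CX3](=[NX2])[NX3]"
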