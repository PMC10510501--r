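# Focused-library classification criteria: substructure requirement /
# exclusion pattern lists plus property-gate and reactive-site-count rules.
# Every list is user-replaceable; these are the shipped defaults.

warheads:
  nitrile: "[CX2]#[NX1]"
  carbamate: "[NX3][CX3](=[OX1])[OX2]"
  boronic_acid: "[BX3]([OX2H1])[OX2H1]"
  acrylamide: "[CX3H2]=[CX3H1][CX3](=[OX1])[NX3]"
  chloroacetamide: "Cl[CX4H2][CX3](=[OX1])[NX3]"
  vinyl_sulfone: "[CX3]=[CX3][SX4](=[OX1])=[OX1]"
  epoxide: "[OX2r3]1[#6r3][#6r3]1"
  aldehyde: "[CX3H1]=[OX1]"

# alpha-amino-acid backbone with a carbon side chain on the alpha carbon;
# the acyl side may be free acid, ester or amide (derivatives).  A bare
# glycine backbone (alpha CH2) does not match.
amino_acid_backbone: "[NX3][CX4H1]([#6;!$([CX3]=[OX1])])[CX3](=[OX1])[OX2,OX1-,NX3]"

# attachment: N9/N1-substituted nucleobase (the glycosidic-type ring
# nitrogen carries a non-hydrogen substituent)
nucleobase_attached:
  purine_n9_subst: "[#6;!c]n1cnc2c1nc[n,c]c2"
  pyrimidinedione_n_subst: "[#6]n1ccc(=O)[nX3]c1=O"
  cytosine_n_subst: "[NX3]c1cc[nX3]([#6])c(=O)n1"

# "unwanted reactive sites" for the general-purpose screening library:
# the electrophile subset of the side-reaction patterns.
unwanted_reactive:
  acyl_halide: "[CX3](=[OX1])[F,Cl,Br,I]"
  sulfonyl_halide: "[SX4](=[OX1])(=[OX1])[F,Cl,Br]"
  aliphatic_halide: "[CX4;!$([CX4](F)(F)F)][Cl,Br,I]"
  anhydride: "[CX3](=[OX1])[OX2][CX3](=[OX1])"
  isocyanate: "[NX2]=[CX2]=[OX1]"
  isothiocyanate: "[NX2]=[CX2]=[SX1]"
  epoxide: "[OX2r3]1[#6r3][#6r3]1"
  aziridine: "[NX3r3]1[#6r3][#6r3]1"
  azide: "[#7]=[#7+]=[#7-]"
  diazonium: "[NX2+]#[NX1]"
  aldehyde: "[CX3H1]=[OX1]"
  michael_acceptor: "[CX3]=[CX3][CX3]=[OX1]"
  peroxide: "[OX2][OX2]"
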