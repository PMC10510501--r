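# Default reaction rule set: four main reaction categories expressed as
# seven named rules (amide, ester, SNAr, Buchwald-Hartwig amination, and the
# catalytic C-C couplings Suzuki, Sonogashira, Heck), plus the side-reaction
# pattern set that vetoes reagent pairings under the condition classes in
# which the flagged group is expected to interfere.
#
# Role patterns are SMARTS on the standardized parent structure; transforms
# are reaction SMARTS (SMIRKS) with two reactant templates and one product.
# leaving: admissible leaving-group formulas (the halide-consuming rules can
# shed HF/HCl/HBr/... depending on which halogen reacted).

role_patterns:
  carboxylic_acid: "[CX3](=[OX1])[OX2H1]"
  amine: "[NX3;H2,H1;!$([NX3][CX3]=[OX1]);!$([NX3][CX3]=[SX1]);!$([NX3][SX4](=[OX1])=[OX1]);!$([NX3]=*);!$([N+]);!$([NX3][OX2H1]);!$([NX3][NX3])]"
  aliphatic_alcohol: "[OX2H1][CX4;!$([CX4](F)(F)F)]"
  # SNAr: halogen on a six-membered aromatic ring carrying >=1 ring nitrogen,
  # or ortho/para to a nitro group (electron-poor positions).
  snar_halide: "[F,Cl,Br;$([F,Cl,Br][c;$(c1naaaa1),$(c1anaaa1),$(c1aanaa1),$(c1c([N+](=O)[O-])aaaa1),$(c1aac([N+](=O)[O-])aa1)])]"
  snar_nucleophile: "[$([NX3;H2,H1;!$([NX3][CX3]=[OX1]);!$([NX3][CX3]=[SX1]);!$([NX3][SX4](=[OX1])=[OX1]);!$([NX3]=*);!$([N+]);!$([NX3][OX2H1]);!$([NX3][NX3])]),$([OX2H1][CX4;!$([CX4](F)(F)F)]),$([SX2H1])]"
  aryl_halide: "[Cl,Br,I;$([Cl,Br,I][c])]"
  boronic_acid: "[BX3]([OX2H1])([OX2H1])[#6]"
  terminal_alkyne: "[CX2H1]#[CX2]"
  mono_olefin: "[CX3H2]=[CX3H1][#6]"
  thiol: "[SX2H1]"

main_reactions:
  amide:
    role_a: carboxylic_acid
    role_b: amine
    condition_class: coupling_agent
    smirks: "[CX3:1](=[OX1:2])[OX2H1].[NX3;H2,H1;!$([NX3][CX3]=[OX1]);!$([NX3][CX3]=[SX1]);!$([NX3][SX4](=[OX1])=[OX1]);!$([NX3]=*);!$([N+]);!$([NX3][OX2H1]);!$([NX3][NX3]):3]>>[C:1](=[O:2])[N:3]"
    leaving: [H2O]
    smoke: {a: "CC(=O)O", b: "CN"}
  ester:
    role_a: carboxylic_acid
    role_b: aliphatic_alcohol
    condition_class: coupling_agent
    smirks: "[CX3:1](=[OX1:2])[OX2H1].[OX2H1:3][CX4;!$([CX4](F)(F)F):4]>>[C:1](=[O:2])[O:3][C:4]"
    leaving: [H2O]
    smoke: {a: "CC(=O)O", b: "OCC"}
  snar:
    role_a: snar_halide
    role_b: snar_nucleophile
    condition_class: base_only
    smirks: "[F,Cl,Br][c;$(c1naaaa1),$(c1anaaa1),$(c1aanaa1),$(c1c([N+](=O)[O-])aaaa1),$(c1aac([N+](=O)[O-])aa1):1].[$([NX3;H2,H1;!$([NX3][CX3]=[OX1]);!$([NX3][CX3]=[SX1]);!$([NX3][SX4](=[OX1])=[OX1]);!$([NX3]=*);!$([N+]);!$([NX3][OX2H1]);!$([NX3][NX3])]),$([OX2H1][CX4;!$([CX4](F)(F)F)]),$([SX2H1]):2]>>[c:1][*:2]"
    leaving: [HF, HCl, HBr]
    smoke: {a: "Clc1ccncc1", b: "CN"}
  buchwald:
    role_a: aryl_halide
    role_b: amine
    condition_class: pd_catalyst
    smirks: "[Cl,Br,I][c:1].[NX3;H2,H1;!$([NX3][CX3]=[OX1]);!$([NX3][CX3]=[SX1]);!$([NX3][SX4](=[OX1])=[OX1]);!$([NX3]=*);!$([N+]);!$([NX3][OX2H1]);!$([NX3][NX3]):2]>>[c:1][N:2]"
    leaving: [HCl, HBr, HI]
    smoke: {a: "Brc1ccccc1", b: "CN"}
  suzuki:
    role_a: aryl_halide
    role_b: boronic_acid
    condition_class: pd_catalyst
    smirks: "[Cl,Br,I][c:1].[BX3]([OX2H1])([OX2H1])[#6:2]>>[c:1][#6:2]"
    leaving: [BClH2O2, BBrH2O2, BH2IO2]
    smoke: {a: "Brc1ccccc1", b: "OB(O)c1ccccc1"}
  sonogashira:
    role_a: aryl_halide
    role_b: terminal_alkyne
    condition_class: pd_catalyst
    smirks: "[Cl,Br,I][c:1].[CX2H1:2]#[CX2:3]>>[c:1][C:2]#[C:3]"
    leaving: [HCl, HBr, HI]
    smoke: {a: "Brc1ccccc1", b: "C#CCC"}
  heck:
    role_a: aryl_halide
    role_b: mono_olefin
    condition_class: pd_catalyst
    smirks: "[Cl,Br,I][c:1].[CX3H2:2]=[CX3H1:3][#6:4]>>[c:1]/[C:2]=[C:3]/[#6:4]"
    leaving: [HCl, HBr, HI]
    smoke: {a: "Brc1ccccc1", b: "C=CCC"}

# Side-reaction patterns.  blocks_under: the condition classes under which
# the group is expected to produce byproducts (and therefore vetoes any
# pairing run under that class).  Groups that are main-reaction roles under
# one class deliberately do not appear here for that class: e.g. a boronic
# acid does not interfere with an amide coupling because no Pd catalyst is
# present.
side_reactions:
  aliphatic_halide:
    pattern: "[CX4;!$([CX4](F)(F)F)][Cl,Br,I]"
    blocks_under: [coupling_agent, base_only, pd_catalyst]
  acyl_halide:
    pattern: "[CX3](=[OX1])[F,Cl,Br,I]"
    blocks_under: [coupling_agent, base_only, pd_catalyst]
  anhydride:
    pattern: "[CX3](=[OX1])[OX2][CX3](=[OX1])"
    blocks_under: [coupling_agent, base_only, pd_catalyst]
  aldehyde:
    pattern: "[CX3H1]=[OX1]"
    blocks_under: [pd_catalyst]
  isocyanate:
    pattern: "[NX2]=[CX2]=[OX1]"
    blocks_under: [coupling_agent, base_only, pd_catalyst]
  isothiocyanate:
    pattern: "[NX2]=[CX2]=[SX1]"
    blocks_under: [coupling_agent, base_only, pd_catalyst]
  epoxide:
    pattern: "[OX2r3]1[#6r3][#6r3]1"
    blocks_under: [coupling_agent, base_only, pd_catalyst]
  aziridine:
    pattern: "[NX3r3]1[#6r3][#6r3]1"
    blocks_under: [coupling_agent, base_only, pd_catalyst]
  free_thiol:
    pattern: "[SX2H1]"
    blocks_under: [coupling_agent, pd_catalyst]
  nh_azole:
    pattern: "[nX3H1]"
    blocks_under: [base_only, pd_catalyst]
  aryl_ester:
    pattern: "[CX3](=[OX1])[OX2][c]"
    blocks_under: [coupling_agent, base_only]
  sulfonyl_halide:
    pattern: "[SX4](=[OX1])(=[OX1])[F,Cl,Br]"
    blocks_under: [coupling_agent, base_only, pd_catalyst]
  michael_acceptor:
    pattern: "[CX3]=[CX3][CX3]=[OX1]"
    blocks_under: [base_only]
  nitro_alkane:
    pattern: "[CX4][N+](=[OX1])[O-]"
    blocks_under: [base_only]
  azide:
    pattern: "[#7]=[#7+]=[#7-]"
    blocks_under: [coupling_agent, base_only, pd_catalyst]
  diazonium:
    pattern: "[NX2+]#[NX1]"
    blocks_under: [coupling_agent, base_only, pd_catalyst]
  imine:
    pattern: "[CX3]=[NX2;!$([NX2]=[CX3][NX3])]"
    blocks_under: [coupling_agent]
  maleimide:
    pattern: "[CX3]1=[CX3][CX3](=[OX1])[NX3][CX3]1=[OX1]"
    blocks_under: [coupling_agent, base_only]
  alpha_halo_carbonyl:
    pattern: "[CX3](=[OX1])[CX4][Cl,Br,I]"
    blocks_under: [coupling_agent, base_only, pd_catalyst]
  hydrazine:
    pattern: "[NX3H2][NX3]"
    blocks_under: [coupling_agent]
  hydroxylamine:
    pattern: "[NX3][OX2H1]"
    blocks_under: [coupling_agent]
  peroxide:
    pattern: "[OX2][OX2]"
    blocks_under: [coupling_agent, base_only, pd_catalyst]
  thioester:
    pattern: "[CX3](=[OX1])[SX2]"
    blocks_under: [coupling_agent, base_only]
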