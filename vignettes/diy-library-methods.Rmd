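---
title: "Building DIY virtual libraries: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building DIY virtual libraries: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`diylib` turns a priced building-block catalog into a one- and two-step
virtual combinatorial library, selects the most cost-efficient block
subset, and characterizes the products for drug-discovery use.  This
vignette explains the model behind each stage, the tunable parameters, the
numerical choices, and what the synthetic test fixtures do and do not
demonstrate about real catalogs.

## The enumeration model

### Reaction rules

Seven named rules cover the four robust reaction categories that dominate
bench practice.  Each rule is a pair of *role* SMARTS patterns (what the
two reagents must carry), a reaction-SMARTS transform (how the product is
assembled), a *condition class* describing the additive/catalyst regime,
and the set of admissible leaving-group formulas:

| rule        | roles                                   | condition class | leaving group |
|-------------|------------------------------------------|-----------------|---------------|
| amide       | carboxylic acid + 1°/2° amine            | coupling_agent  | H2O           |
| ester       | carboxylic acid + aliphatic alcohol      | coupling_agent  | H2O           |
| snar        | electron-poor aryl halide + N/O/S nucleophile | base_only  | HF/HCl/HBr    |
| buchwald    | aryl halide + 1°/2° amine                | pd_catalyst     | HCl/HBr/HI    |
| suzuki      | aryl halide + boronic acid               | pd_catalyst     | X–B(OH)2      |
| sonogashira | aryl halide + terminal alkyne            | pd_catalyst     | HX            |
| heck        | aryl halide + monosubstituted olefin     | pd_catalyst     | HX            |

Design choices a reader should know about:

* **"Electron-poor" for SNAr** is encoded structurally: the halogen must
  sit on a six-membered aromatic ring containing at least one ring
  nitrogen, or ortho/para to a nitro group.  This is a deliberately
  conservative operationalization of a continuous electronic property.
* **Buchwald–Hartwig scope** is restricted to aryl halide + amine; broader
  N/O couplings exist but are less uniform in robustness.
* **Heck regio- and stereochemistry**: the aryl group is installed at the
  terminal carbon and the new double bond is written E-configured, the
  dominant outcome for monosubstituted olefins.
* **Leaving groups are sets, not single formulas**: a halide-consuming rule
  can shed HF, HCl or HBr depending on which halogen reacted, so the
  mass-balance invariant is "combined reagent formula minus product
  formula is *one of* the rule's admissible leaving formulas".
* **Multiple equivalent sites**: the transform is applied at every matching
  site combination and the products deduplicated by InChI; a per-pair cap
  (default 8 products) guards against pathological polyfunctional reagents.

### Side reactions and the compatibility decision

Real enumeration engines reject most reagent pairs.  `diylib` ships 23
documented side-reaction patterns (acyl and sulfonyl halides, anhydrides,
aliphatic halides, epoxides and aziridines, isocyanates, azides, free
thiols, N–H azoles, labile aryl esters, Michael acceptors, and others),
each annotated with the condition classes under which it is expected to
interfere.  A pairing under rule *R* is allowed iff

1. the two molecules carry *R*'s two role patterns (either assignment);
2. neither molecule carries a side pattern whose `blocks_under` includes
   *R*'s condition class; and
3. no *other* main reaction of the same condition class is simultaneously
   possible across the pair (the **ambiguity veto**: an acid plus an
   aminoalcohol is rejected for amidation because esterification proceeds
   under the same coupling-agent conditions, and the product would not be
   clean).

Scoping vetoes by condition class reproduces the practical exceptions: a
boronic acid on the amine partner does **not** veto an amide coupling —
without a Pd catalyst there is no Suzuki pathway — while an aliphatic
halide interferes everywhere.  The shipped pattern list is intentionally
a documented, extensible default (a YAML file the user can replace);
proprietary engines use hundreds of patterns, so absolute product counts
from different pattern sets are not comparable, but the mechanism is the
same.  The ambiguity veto is also re-applied at step 2 to intermediates
bearing residual handles; this may undercount relative to engines that
relax it, which we accept for consistency of the pairing semantics.

### Two-step pool logic

Step 1 tests every unordered pair of catalog blocks (including a block
with two copies of itself, which a physical stockroom allows; disable with
`self_pairing = FALSE`).  Step 2 re-scans each step-1 product for residual
handles and pairs it against the **original blocks only** — never
intermediate × intermediate.  Every product records its routes (ordered
rule applications plus reagent ids; three blocks for two-step routes), and
identity is byte-exact standard InChI.  Tautomers are deliberately *not*
canonicalized beyond InChI's own tautomer layer, and stereo-bearing versus
flat duplicates remain distinct, because InChI distinguishes them.  A
molecule reachable at both steps keeps all routes with the one-step route
preferred.  In per-(rule, step) tabulations a product counts once in every
cell that appears in any of its routes, so a two-step product contributes
to both its first-step and its second-step cell; the unique-product total
is reported separately.

## Cost-efficient block selection

The *reaction score* of block *b* against the current surviving product
set *P* is `|{p in P : b in blocks(p)}| / price(b)` — products per
currency unit.  Selection iteratively removes the single lowest-scoring
block, drops all products whose routes use it, and recomputes every score
on the reduced set.  This is exact bookkeeping, not a heuristic
approximation: the implementation keeps an inverted product–block index
with lazy deletion, and its contract (tested exhaustively on small
catalogs) is equality with from-scratch recomputation at every iteration.

Ties on the lowest score are broken by removing the higher-priced block,
then the lexicographically greatest id — keep the cheaper reagent, stay
deterministic.

The products-vs-budget curve (one point per iteration plus the initial
state) summarizes the trade-off.  Its **knee** is located by min–max
normalizing both axes, lightly smoothing the product axis (running mean,
window 3), and taking the point of maximum deviation from the straight
chord joining the endpoints.  For a curve with a single slope break this
deviation peaks exactly at the break (it is the discrete-curvature
maximum); unlike second differences it is robust to sampling noise, which
matters because elimination curves are step functions.  A curve with no
deviation above `1e-3` (normalized) is flagged degenerate and the
full-catalog endpoint returned with a warning.

Route costs are estimated as the sum of building-block prices plus a
per-reaction reagent/catalyst overhead range (default 0.1–2.5 currency
units) plus a per-step solvent constant (default 1.0), minimized over a
product's recorded routes.

## The descriptor panel and gates

`compute_profile()` returns 19 descriptors: molar mass, logP
(Wildman–Crippen atom contributions), polar surface area (extended Ertl
TPSA including S and P contributions, the convention used by the OpenBabel
toolkit), H-bond acceptors (acceptor perception by default; Lipinski N+O
counting available via `hba_mode`), H-bond donors, rotatable bonds, heavy
atom count, ring count, fraction of sp3 carbons, molar refractivity,
aromatic and aliphatic ring counts, chiral centers (assigned plus
unassigned), acidic and basic group counts from configurable SMARTS lists
(carboxylic/sulfonic/phosphonic acids and tetrazoles; aliphatic amines,
amidines, guanidines — patterns are mutually exclusive so a guanidine
counts once), their sum, noncyclic amide count, O+N atom count, and
heteroatom ratio (non-carbon heavy atoms over heavy atoms).

Gate thresholds ship as a YAML file and are fully configurable.  Defaults
are the canonical literature definitions — rule of five (mass ≤ 500,
logP ≤ 5, donors ≤ 5, acceptors ≤ 10), rule of three (mass < 300,
logP ≤ 3, donors ≤ 3, acceptors ≤ 3, rotatable bonds ≤ 3, PSA ≤ 60),
lead-like (200 ≤ mass ≤ 450, −3.5 ≤ logP ≤ 4.5, rings ≤ 4, rotatable
bonds ≤ 10).  Boundary semantics are documented and tested: the
rule-of-three mass bound is a strict `<`, every other bound inclusive.
Under these defaults rule-of-three compliance implies rule-of-five
compliance.

**Cross-implementation agreement.** The test suite compares the panel
against the independent OpenBabel implementation (via ChemmineR).  Count
descriptors, molar mass, PSA and refractivity agree (counts exactly,
continuous values within ±15%).  logP does **not** reliably agree within
±15%: the two Wildman–Crippen implementations type amine nitrogens and
S(VI) sulfur differently, producing systematic offsets of ~0.7 log units
per primary amine and up to ~1.8 on sulfonamides, and molecules with
logP ≈ 0 make a relative band meaningless.  We report this honestly
rather than widening the band: treat absolute logP values as
estimator-specific, and gate comparisons between libraries computed with
the same estimator.

## Focused subsets

Classification criteria (warhead patterns, the α-amino-acid backbone, the
N-substituted nucleobase patterns, the unwanted-reactive-site list) ship
as YAML defaults and are user-replaceable; detailed published criteria can
be keyed in directly.  Notable semantics:

* **Amino-acid derivatives** require an α-carbon bearing one hydrogen and
  a carbon side chain between the amine and the acyl group; bare glycine
  backbones (α-CH2) never qualify — they would otherwise swamp the subset.
* **DEL building blocks** are classified by the number of distinct
  main-reaction handles (2 or 3 sites); single-handle capping blocks are
  computed but not labelled, mirroring their deliberate omission from
  reporting.
* **Covalent warheads** (nitrile, carbamate, boronic acid, acrylamide,
  chloroacetamide, vinyl sulfone, epoxide, aldehyde) are split into
  fragment-sized (rule-of-three) and drug-like (rule-of-five) subsets.
* **The general screening subset** requires passing the published PAINS
  families A/B/C (via the RDKit filter catalog; a user pattern list is
  also accepted) *and* carrying none of the unwanted reactive sites
  (default: the electrophile subset of the side-reaction patterns).
* **Bioactives** are exact InChI matches against a user-supplied annotated
  file; no activity database is queried.

## Chemical space and novelty

Morgan fingerprints of radius 2 folded to 2048 bits (the ECFP4
configuration; folded length configurable) feed a Barnes–Hut t-SNE
(`Rtsne`, theta 0.5, Euclidean distances on the binary matrix, random
initialization, default perplexity 70, 1000 iterations).  Embeddings are
seed-deterministic; internally molecules are embedded in key-sorted order
so that permuting the input with the same seed permutes the coordinates
identically.  Perplexities too large for the input are auto-reduced with a
warning.  For large libraries, `subsample_by_subset()` draws a seeded
fixed-size sample per subset (default 1000) before embedding.

Novelty against reference collections is a byte-exact standard-InChI
membership test — no fuzzy matching — so the novelty fraction is exactly
`1 − |overlap| / |products|`.

## The synthetic catalog generator

`generate_catalog()` builds deterministic priced catalogs from a fixed
pool of ~25 inert ring/chain cores (benzene/naphthalene/biphenyl
derivatives, cycloalkanes, short chains, an oxane; chloroazine cores for
heteroaryl halides) decorated with requested handle fragments
(aminomethyl, carboxyl, hydroxymethyl, aryl bromide, boronic acid,
terminal alkyne, vinyl, thiomethyl).  Cores are chosen to carry no side
pattern and no role of their own, so a block's reactivity is exactly its
planted handles — which is what makes the combinatorial oracles countable
by hand.  Handle counts use largest-remainder allocation (any remainder of
the mix becomes inert blocks), a requested fraction of blocks receives a
second handle, and prices are drawn uniformly (default 4.5–10 per gram,
the reported price band of real sub-10-unit building blocks; a log-uniform
option exists).  The same seed always reproduces the same catalog.

What the fixtures do *not* emulate: real supplier catalogs have skewed
price distributions, correlated functionality (amino acids, heterocycles
with several weakly reactive sites), salts and solvates, and far more
diverse scaffolds.  Passing the oracle tests therefore demonstrates the
*mechanics* — pairing logic, dedup, bookkeeping, selection — not the
absolute product counts or subset percentages of any real catalog.

A frozen nine-block "known-answer" micro-world (three acids, four amines,
an aryl bromide, an arylboronic acid) anchors regressions: its full
two-step library (33 products: 12 step-1 amides, 4 aminations, 1 biaryl,
16 step-2 products) and its elimination trace were computed with a naive
pair-by-pair oracle and stored as plain-text fixtures.

## Problem sizes and determinism

The shipped tests run, on one CPU, two-step enumerations of 8–30-block
catalogs (seconds each), a 100-block end-to-end pipeline (about four
minutes including profiling and classification), fifty elimination-oracle
replays, seven-rule mass-balance sweeps of 1000+ pairings per rule, and a
3000-point t-SNE (under a minute).  All randomness flows through explicit
seeds; enumeration results are independent of catalog order and of the
number of work partitions, and this is asserted, not assumed.

## Known limitations

* Product counts depend on the side-pattern list; the shipped 23 patterns
  are a floor, not a ceiling.  Users approximating a proprietary engine
  should expect to extend the list substantially.
* SNAr activation is structural, not electronic; strongly deactivated
  azines and activated carbocycles outside the nitro rule are mis-scoped.
* Reaction yields, regioselectivity beyond the encoded rules, and
  protecting-group chemistry are out of scope; routes are synthetic
  *feasibility* claims only.
* Absolute logP values are estimator-specific (see above).
* Three-step and longer enumeration, retrosynthesis of external
  molecules, and supplier-API price lookups are out of scope.
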