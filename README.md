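# diylib — do-it-yourself virtual combinatorial chemical libraries

Medicinal-chemistry groups can build large, novel virtual screening
libraries in-house instead of licensing them: start from a few hundred
cheap, purchasable building blocks, enumerate every product reachable in
one or two robust reaction steps, and keep the block subset that buys the
most products per currency unit. `diylib` implements that workflow end to
end for R:

* **Forward enumeration.** Seven named reaction rules covering the four
  robust categories used at the bench — amide and ester formation
  (coupling-agent conditions), nucleophilic aromatic substitution
  (base-only), and Buchwald–Hartwig, Suzuki, Sonogashira and Heck couplings
  (Pd catalysis) — are applied to every reagent pair as reaction SMARTS.
  A pairing is enumerated only if the two molecules carry the rule's role
  patterns, carry no *side-reaction* pattern that interferes under that
  rule's condition class, and no *other* main reaction of the same
  condition class is simultaneously possible (the ambiguity veto).  The
  condition-class scoping reproduces the practical exceptions: a boronic
  acid never blocks an amide coupling (no Pd present), while an aliphatic
  halide blocks everything.  Step 2 pairs first-step intermediates against
  the *original* blocks only, yielding three-block routes with full
  provenance.
* **Cost-aware selection.** Each block's *reaction score* is the number of
  surviving end-products it contributes to divided by its price per gram:

  `score(b) = |{products whose routes use b}| / price(b)`

  The lowest-scoring block is eliminated and all its products dropped,
  iterating until the requested count remains; the products-vs-budget curve
  and its knee (maximum deviation from the end-to-end chord after min–max
  normalization) summarize the trade-off.
* **Profiling and focused subsets.** A 19-descriptor physicochemical panel
  (molar mass, logP, PSA, H-bond donors/acceptors, rotatable bonds, heavy
  atoms, ring counts, fsp3, refractivity, chiral centers, acid/base group
  counts, noncyclic amides, O+N count, heteroatom ratio) with rule-of-five,
  rule-of-three and lead-likeness gates; classification into focused
  subsets (DNA-encoded-library blocks with 2 or 3 reactive handles,
  covalent warheads split fragment/drug-like, amino-acid derivatives with
  the glycine backbone excluded, nucleotide derivatives, known bioactives
  by exact InChI match, and a PAINS-screened general-purpose set).
* **Novelty and chemical space.** Byte-exact InChI membership tests against
  reference sets, ECFP4-type Morgan fingerprints, and seed-deterministic
  Barnes–Hut t-SNE maps (default perplexity 70).

Chemistry primitives (parsing, canonical SMILES/InChI, substructure
matching, reaction application, descriptors, fingerprints, the PAINS
catalog) are computed by a bundled RDKit worker process that the package
manages transparently; all enumeration, selection and classification logic
is in R.

## Worked example

```r
library(diylib)

rules  <- load_rule_set()                 # 7 main reactions, 23 side patterns
spec   <- catalog_spec(20, c(carboxylic_acid = 0.3, amine = 0.3,
                             aryl_halide = 0.2, boronic_acid = 0.2),
                       seed = 42)
blocks <- generate_catalog(spec)          # priced, standardized catalog

lib <- enumerate_library(blocks, rules, steps = 2)
nrow(lib)
#> [1] 250
tab <- tabulate_by_rule(lib)
tab[tab$n_products > 0, ]
#>        rule step n_products
#> 1     amide    1         30
#> 4  buchwald    1        204
#> 5    suzuki    1         16
#> 8     amide    2        120
#> 11 buchwald    2         60

trace <- eliminate(blocks, lib, 10)       # keep the 10 best-scoring blocks
tail(budget_curve(trace), 3)
#>    n_blocks n_products total_price
#> 9        12        145       87.04
#> 10       11        120       78.82
#> 11       10         96       70.14
```

250 unique products from 20 blocks: the count is the deduplicated InChI
key set; the aryl-halide-rich mix makes Buchwald aminations dominate
step 1 (a product reachable in two steps also counts in the cell of its
first-step rule).  The budget curve shows that the 10 retained blocks
(70.14 price units) still reach 96 products.

Classification and mapping continue from the same objects:

```r
prof  <- compute_profile(lib)
gates <- apply_gates(prof)            # ro3 / lead_like / ro5 flags
mean(gates$ro5)
labels <- classify(lib, prof, rules)  # focused subsets incl. PAINS screen
emb <- embed_tsne(fingerprint(lib), perplexity = 70, seed = 1)
```

A thin command-line front end for every stage (`diy enumerate`,
`diy select`, `diy profile`, `diy classify`, `diy novelty`, `diy embed`,
`diy fixtures make`, …) ships in `inst/scripts/diy`.

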