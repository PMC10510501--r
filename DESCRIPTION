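Package: diylib
Title: Do-It-Yourself Virtual Combinatorial Chemical Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-synthetic enumeration of one- and two-step virtual
    chemical libraries from priced building-block catalogs.  Reagent pairs
    are combined under main-reaction rules (amide and ester formation,
    nucleophilic aromatic substitution, Buchwald-Hartwig amination, and the
    Suzuki, Sonogashira and Heck couplings) gated by side-reaction
    incompatibility patterns scoped to condition classes.  Includes
    cost-aware greedy building-block selection by reaction score
    (products-per-price), route cost estimation, a 19-descriptor
    physicochemical panel with rule-of-five, rule-of-three and lead-like
    gates, focused-library classification (DNA-encoded-library building
    blocks, covalent warheads, amino-acid and nucleotide derivatives, PAINS
    screening), InChI exact-match novelty checking, and ECFP4/t-SNE
    chemical-space maps.  Chemistry primitives are computed by a bundled
    RDKit worker process.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    processx,
    yaml,
    Matrix,
    Rtsne,
    stats,
    utils
Suggests:
    ChemmineR,
    ChemmineOB,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with the rdkit package, discoverable as
    'python' on the PATH (configurable via option 'diylib.python').
Config/testthat/edition: 3
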