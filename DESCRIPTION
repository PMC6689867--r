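Package: molgru
Title: Generative GRU Language Model for Quasi-Biogenic Molecule Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains a gated-recurrent-unit (GRU) language model on SMILES
    strings of biogenic (natural-product) compounds and samples it to build
    quasi-biogenic virtual libraries with stereochemistry preserved.
    Provides bracket-aware SMILES tokenization, corpus curation against the
    organic element subset and heavy-atom size limits, transfer learning for
    chemotype-biased focused libraries, and a validation battery covering
    validity, uniqueness, novelty, reproduction of held-out molecules,
    framework-scaffold diversity, circular-fingerprint nearest-neighbour
    similarity, natural-product-likeness scoring, and physicochemical
    profiling with t-SNE maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
SystemRequirements: OpenBabel (the obabel executable on the PATH)
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
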