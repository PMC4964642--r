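Package: pcnfold
Title: Protein Contact Network Observables for Folding-State Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds protein contact networks (PCNs) from C-alpha traces and
    computes network observables that discriminate two-state from multi-state
    folding kinetics: the ensemble-entropy ratio S_R from maximum-entropy
    weighted-network ensembles constrained on strength (and degree) sequences,
    Laplacian eigenvalue features of the backbone-reduced PCN, the
    inter-residue link density R0, and classical comparators (chain length,
    mean Kyte-Doolittle hydropathy, contact order, long-range contact order).
    Includes Gaussian discriminant classification with homology-grouped
    k-fold cross-validation and Matthews correlation reporting, deterministic
    synthetic-structure generators for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
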