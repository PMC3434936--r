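Package: paeML
Title: Maximum-Likelihood Taxon-Area Analysis of Species Presence/Absence
    Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers area cladograms from binary taxon-area (area x species)
    presence/absence matrices using a symmetric two-state Mk model with
    discrete-gamma rate heterogeneity and an optional invariant-character
    class, alongside Fitch parsimony and UPGMA comparators. Provides
    all-zero-outgroup and Lundberg rooting, heuristic tree search with
    nonparametric bootstrap, hypothetical-extinct-taxa (all-zero column)
    augmentation scenarios, and stochastic character mapping of individual
    species histories on a fixed area tree, together with a seeded synthetic
    data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    ape (>= 5.0),
    phangorn
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
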