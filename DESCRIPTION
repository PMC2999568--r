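Package: hmgtrace
Title: Domain Profiling, Phylogenetics and Motif Scanning for the Fungal
    Mating-Type alpha1 Domain within the HMG-Box Superfamily
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether the fungal mating-type alpha1 domain is a
    derived subclass of the HMG-box superfamily. Provides core-region
    profiling of protein domain alignments (coverage filtering, gappy-column
    removal, positional frequency profiles, consensus sequences), pairwise
    consensus comparison with Karlin-Altschul E-values, maximum-likelihood
    phylogenetics under the LG model with discrete-gamma rate heterogeneity
    (Felsenstein pruning, neighbor-joining start, NNI hill-climbing,
    RELL-based expected-likelihood-weight edge supports, KH and SH topology
    tests), marginal maximum-likelihood ancestral sequence reconstruction,
    PROSITE-style motif scanning, and a seeded synthetic-data generator that
    emulates a four-class HMG-like domain family with class-specific core
    truncations and a planted downstream motif.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
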