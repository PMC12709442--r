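Package: transpoloop
Title: Clustered Transposon Insertion and Chromatin Unfolding
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models and quantifies the feedback between transposon
    insertion and three-dimensional chromatin folding. Provides genomic
    statistics for repeat annotations (pairwise-distance distributions
    against the closed-form uniform-placement density, one-dimensional
    DBSCAN cluster calling, open-chromatin overlap, Mann-Whitney group
    comparisons, and TRX dinucleotide flexibility scoring with
    flexibility-accessibility and flexibility-age regressions), a
    coarse-grained Langevin-dynamics polymer model of a self-attracting
    chromatin domain in which insertions locally abolish self-attraction
    (with prescribed-adjacency and explicit-transposase insertion
    processes), estimators of unfolding (radius of gyration, Hill-curve
    fits, maximum-likelihood placement adjacency, radial insertion
    metrics, core-shell classification, replicated parameter scans), and
    a synthetic-data layer generating all fixtures with controlled
    clustering, coupling and dinucleotide composition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    minpack.lm,
    Biostrings,
    IRanges,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
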