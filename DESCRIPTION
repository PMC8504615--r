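Package: rarebic
Title: Rare Cell Subpopulation Discovery by Constrained Max-Sum Submatrix Biclustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies rare, highly specific subpopulations of cells in
    single-cell expression data by jointly selecting a small set of cells and
    a set of marker genes. The selection maximizes a max-sum submatrix
    objective penalized by out-of-cluster expression of the selected genes,
    under an upper bound on the fraction of negative (non-expressed) entries
    inside the bicluster. Includes log-normalization and gene prevalence
    filtering, a breadth-first beam search with an exhaustive oracle for
    small instances, a top-k strategy for finding several disjoint
    subpopulations, a planted-subpopulation simulator with negative-binomial
    counts and dropout, precision/recall evaluation of controlled
    experiments, matrix readers (TSV/CSV/MatrixMarket) and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
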