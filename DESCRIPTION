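Package: mitoamt
Title: Label-Free AMT-Tag Proteomics: Differential Expression and
    Network Analysis for Two-Group Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end, simulation-backed pipeline for label-free
    LC-MS proteome comparison built on accurate mass and time (AMT) tags.
    Per-run unique-mass-class (UMC) feature tables are compiled into a
    master AMT database (average mass, median normalized elution time),
    unidentified features are assigned peptide identities within mass and
    NET tolerances, abundances are aligned across runs, quantile
    normalized and collapsed to subjects, and differential expression is
    called with a composite permutation test (Student's t and log2-median
    ratio, Stouffer-combined, Storey q-values) rolled up to proteins.
    Includes hypergeometric GO enrichment, protein-protein interaction
    subnetwork assembly, and a synthetic-cohort generator with planted
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    limma,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
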