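Package: paretoqsar
Title: Pareto-Optimal Model Identification for QSAR Model Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies the most reliable predictive model for a query
    chemical compound from a collection of pre-existing QSAR models by
    balancing two criteria: structural similarity (Tanimoto distance on
    binary fingerprints) and model error on known chemicals.  Provides a
    randomized divide-and-conquer algorithm for two-dimensional Pareto
    fronts with a brute-force oracle, n-Pareto neighbourhoods, average-
    and centroid-based model identification (n-APMI, n-CPMI) plus a
    nearest-neighbour baseline (DMS), leave-one-out evaluation against an
    oracle selector with classification and regression reports (Q2, MAE,
    RMSE), pairwise similarity-versus-activity summaries, bundled linear
    narcosis QSAR models for IGC50, and a clustered synthetic dataset
    generator for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
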