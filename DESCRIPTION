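Package: herbnet
Title: Integrative Network-Pharmacology Screening for Multi-Herb Formulas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for integrative pharmacology of
    multi-herb preparations: formula/adduct-based annotation of mass-spectrometry
    features with neutral-loss fragment assignment, differential-expression and
    counter-regulation screening of treatment contrasts, median-threshold
    two-stage topological hub-gene extraction from compound-target-disease
    interaction networks, drug-likeness filtering and dual-median key-constituent
    selection, and hypergeometric pathway over-representation analysis. Seeded
    synthetic-data generators plant ground truth for every stage so the whole
    pipeline is reproducible without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
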