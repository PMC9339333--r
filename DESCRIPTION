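Package: wheatTriads
Title: Homoeolog Retention, Expression Divergence and Mutation Load of
    Transcription Factors in Polyploid Wheat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for homoeolog retention of transcription
    factor (TF) families across the two polyploidization steps of bread
    wheat. Classifies homoeolog groups (diads in tetraploid, triads in
    hexaploid) from homoeology tables, computes per-family retention and
    the loss-adjusted normalized retention statistic, detects tandem
    duplication events from gene-order adjacency, quantifies homoeolog
    expression divergence and coexpression across tissues, and estimates
    per-individual deleterious mutation load from SIFT-annotated exome
    SNPs in a cohort. Includes a synthetic-study generator that emulates
    the statistical structure of all required inputs so the whole
    pipeline is testable end to end, plus oracle-tested statistical
    primitives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
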