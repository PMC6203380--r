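Package: crosstum
Title: Cross-Species Tumor-Suppressor Screen Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing in vivo RNAi tumor-suppressor screens and
    translating fly hits to human cancer genomics. Implements Z-score hit
    calling from pupariation counts, ortholog expansion with platform
    restriction, tumor-suppressor-oncogene scores (TSOS) over paired
    tumor/normal expression with a gene-set resampling null, first-degree
    binding-partner expansion with hypergeometric gene-set enrichment and
    annotation-graph condensation, and gene-signature patient stratification
    by repeated k-means with log-rank survival and mutation-enrichment tests.
    Includes a synthetic-data module that generates every input the pipeline
    consumes, so the full chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    survival,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
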