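Package: grcfinder
Title: Discovery and Characterization of Germline-Restricted Chromosomes from
    Tissue-Paired Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterizing a germline-restricted
    chromosome (GRC) from paired germline (testis) and somatic (kidney)
    sequencing of the same individuals. Implements a three-channel classifier
    for germline-specific linked reads (germline-only assembly regions,
    tissue-specific diagnostic k-mers derived from SNPs, and GRC-restricted
    repeats) followed by molecular-barcode expansion; soma-subtracted coverage
    normalization and per-window copy-number estimation with a duplication-
    corrected GRC size estimate; cross-species homology and A-chromosomal
    origin classification of GRC sequence; gene completeness and
    pseudogenization scoring with expression analysis; and estimation of GRC
    physical size from meiotic-spread measurements by log-log karyotype
    regression. A seeded synthetic-data generator with full truth tables and a
    minimal exact-seed read mapper make the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
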