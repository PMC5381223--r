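Package: methage
Title: Whole-Genome Bisulfite Methylation Profiling and Differential
    Methylation Analysis for Pooled Two-Group Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for whole-genome bisulfite
    sequencing (WGBS) methylation analysis of pooled two-group designs,
    as used in ageing studies of chicken breast muscle. Reads
    Bismark-style per-cytosine reports, estimates the bisulfite
    non-conversion rate from an unmethylated spike-in, identifies true
    methylation sites with an exact binomial test against the
    non-conversion null, computes conversion-corrected methylation
    levels, profiles methylation by sequence context and functional
    element, detects differentially methylated regions (DMRs) with a
    1 kb / 100 bp sliding-window Fisher scan, annotates DMRs to gene
    elements, and integrates promoter methylation with expression and
    phenotypic traits to nominate candidate genes. A synthetic-data
    module simulates two-group bisulfite count data with planted DMRs
    and coupled expression so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
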