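Package: methtrace
Title: Multigenerational Persistence Analysis of Germline DNA Methylation
    Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding whether endocrine-disruptor-induced DNA
    methylation changes in the fetal male germline persist across
    generations. Implements percentile-based positive-probe calling and
    gap-tolerant peak detection on tiling-array log2(MIRA/input) signal,
    replicate consensus peaks, bidirectional differential-methylation
    tests combining a fold-change cutoff with Fisher's exact test, a
    four-level intersection framework for transgenerational persistence,
    region-average methylation scoring at imprinted differentially
    methylated regions and retrotransposon flanks, allele-specific
    quantification with odds-scale skew calibration, mixing-series
    linearity checks and Bonferroni-familied group comparisons,
    differential-expression overlap and direction-enrichment analysis,
    and synthetic-data generators emulating the assumed data structure
    so every stage is testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
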