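Package: aseqc
Title: Sample-Level Quality Control for Allele-Specific Expression Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Flags RNA-seq samples with globally aberrant allele-specific
    expression (ASE). Per sample, gene-level allelic counts are modelled with
    a uniform/binomial-logit-normal mixture; the maximum-likelihood estimate
    of the logit-normal standard deviation (the aseQC score, sigma(BLN))
    summarises extra-binomial allelic dispersion, which is inflated by
    genotype-RNA mismatch contamination and other sample-quality failures.
    Cohort outliers are called with a medcouple skew-adjusted boxplot
    threshold (sigma_t). Includes readers for long, matrix-pair and
    phASER-style allelic count tables, most-expressed-SNP gene aggregation,
    a synthetic cohort generator with tunable contamination, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
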