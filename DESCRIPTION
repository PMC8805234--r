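Package: ntmr
Title: Mendelian Randomisation with Maternal Non-Transmitted-Allele Polygenic Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for one-sample Mendelian randomisation of maternal exposures
    on offspring outcomes using polygenic instruments built from maternal
    alleles that were not transmitted to the offspring. Includes a
    mother-father-offspring trio simulator with known causal structure
    (Mendelian transmission, familial confounding, parental direct genetic
    effects, assortative mating, block linkage disequilibrium), deterministic
    duo-based resolution of transmitted and non-transmitted maternal dosages,
    polygenic score construction (allele harmonisation, LD clumping and
    p-value thresholding, weighted scoring, within-stratum standardisation),
    an estimator suite (confounder-adjusted multivariable regression,
    two-stage least squares, Wald ratio with Taylor-series standard errors,
    per-SNP Wald ratios), fixed- and random-effects meta-analysis, a
    bootstrap-covariance z-test for multivariable-versus-MR differences, and
    pleiotropy diagnostics (MR-Egger, between-SNP Cochran's Q, instrument
    validity screens, effect-size-stratified MR).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
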