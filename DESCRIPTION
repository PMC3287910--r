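Package: wavescore
Title: Wavelet-Based Multilocus Score Tests for Rare-Variant Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Association testing between windows of rare nonsynonymous
    variants and quantitative or binary traits using a multilocus score
    statistic computed on wavelet-denoised, frequency-weighted genotypes.
    Each individual's weighted multilocus genotype is transformed with a
    discrete wavelet transform, shrunk by level-dependent empirical Bayes
    posterior-median thresholding under a spike-and-slab Laplace prior, and
    inverted before testing. Includes principal-component adjustment for
    population stratification, trait residualization on covariates,
    permutation-based empirical p-values with Bonferroni and max-statistic
    family-wise corrections, a simulation comparing the two corrections,
    and a synthetic-cohort generator with Balding-Nichols substructure for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    tibble,
    dplyr,
    readr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
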