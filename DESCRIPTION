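Package: wakecue
Title: Simulation and Analysis of Awake Targeted Memory Reactivation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing object-location cueing
    (awake targeted memory reactivation) experiments. Provides a generative
    simulator of the full experimental session (training to criterion,
    immediate and delayed placement tests, a lexical-decision cover task with
    brief cue re-exposures, and a cue-discrimination test), a two-parameter
    mixture model of spatial memory (uniform guessing plus isotropic 2D
    Gaussian recall) fitted by constrained maximum likelihood, balanced
    cued/uncued assignment by exhaustive partition search, bisquare
    iteratively reweighted least squares regression with permutation-based
    inference, and repeated-measures group analyses (ANOVA, paired
    contrasts, a PCA learning factor, and chi-squared cue-discrimination
    classification).
License: MIT + file LICENSE
Encoding: UTF-8
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
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    broom,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
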