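Package: rrstpipe
Title: Simulation and Analysis Pipeline for Respiratory Resistance
    Discrimination Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing two-alternative forced-choice
    respiratory resistance sensitivity task (RRST) experiments in clinical
    group designs. Provides a Bayesian adaptive (psi) staircase for stimulus
    placement, maximum-likelihood Weibull psychometric-function fitting with
    75 percent-correct thresholds and sensitivity scores, type-II ROC
    (AUROC2) metacognition scoring, drift-diffusion decomposition of choices
    and response times with hierarchical Bayesian estimation and DIC model
    comparison, a synthetic-cohort generator with controllable group effects
    for parameter-recovery studies, and the group-contrast statistics layer
    (Welch t, Mann-Whitney, chi-squared, Pearson correlations, effect sizes,
    multiplicity adjustment, interaction regressions).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
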