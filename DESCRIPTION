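Package: twostagerl
Title: Simulation, Fitting, and Analysis of a Two-Stage Reversal Learning Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying the balance of model-free and model-based
    reinforcement learning in a two-stage Markov decision task with uncued
    reward-probability reversals. Provides the task engine (70/30 transition
    structure, block-wise reversal schedule), generative agents (hybrid,
    pure model-free, pure model-based, random, perseverating) for building
    synthetic cohorts, a hybrid value-update model with valence- and
    transition-dependent increments and a softmax choice rule, per-subject
    maximum-likelihood fitting via multi-restart Nelder-Mead, and the
    behavioral analysis battery: perseverator exclusion, stay-probability
    tables, mixed-design ANOVA, group comparisons, and regression/ANCOVA on
    fitted parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
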