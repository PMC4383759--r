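Package: qsmart
Title: Q-Learning for Two-Stage Sequential Multiple Assignment Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of optimal two-stage dynamic treatment regimes from
    sequential multiple assignment randomized trial (SMART) data by linear
    Q-learning with backward induction, in the design used by acute
    bipolar-depression SMART pathways: a three-arm first stage, a responder
    rule, and re-randomization of placebo non-responders only.
    Includes a synthetic cohort generator with known generative truth,
    multiple imputation by chained equations (predictive mean matching and
    logistic conditionals), forward stepwise model selection minimizing BIC
    averaged over imputations, nonparametric bootstrap confidence intervals
    with an optional non-regularity soft-threshold correction, and
    inverse-probability-weighted estimation of regime values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    nnet,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
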