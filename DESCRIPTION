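Package: svyboost
Title: Survey-Weighted Evaluation of Gradient Boosting Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how complex-survey sampling weights affect
    gradient-boosted classification. Provides a synthetic complex-survey
    data generator with informative log-normal sampling weights, survey-
    weighted classification metrics (sensitivity, positive predictive
    value, F1) with percentile bootstrap confidence intervals, a weighted/
    unweighted model-configuration engine built on xgboost with stratified
    cross-validation and randomized hyperparameter search, a three-scenario
    evaluation framework comparing weighted and unweighted model
    configuration and scoring against a weighted gold standard, and a
    seeded simulation-grid runner with tidy outputs and plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
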