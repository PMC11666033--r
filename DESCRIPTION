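Package: prevmetrics
Title: Consistency of Binary-Classification Metrics Across Prevalence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how consistently confusion-matrix metrics and
    the rank-based AUC evaluate and rank binary classifiers as the prevalence
    of the positive class changes while sample size and inter-variable
    relationships are held constant. Provides the metric catalogue in both
    count form and (n, prevalence, TPR, TNR) form, a constant-n class-swap
    prevalence sweep simulator, model fitting and random-guess baselines, rank
    and variance analyses with variance-homogeneity tests, an all-thresholds
    analysis with incremental threshold averaging, and a synthetic generator
    for recidivism-style tabular data with a calibrated logistic outcome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    class,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
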