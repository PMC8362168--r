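Package: calibrisk
Title: Probability-Calibrated Clinical Risk Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Builds and evaluates probability-calibrated versions of common
    machine-learning risk classifiers (naive Bayes, logistic regression,
    random forest, support vector machine, feedforward neural network) for
    binary clinical outcomes such as 3-year relapse in diffuse large B-cell
    lymphoma.  Implements three calibration maps -- Platt scaling with
    smoothed targets, pair-adjacent-violators isotonic regression, and
    shape-restricted polynomial regression solved as a constrained quadratic
    program -- together with the discrimination and calibration metrics used
    to compare them (AUC, Hosmer-Lemeshow test, expected and maximum
    calibration error, Brier score), a synthetic cohort generator with a
    known logistic outcome model, and a repeated stratified hold-out
    experiment driver with leakage-free out-of-fold calibration training
    sets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    quadprog,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
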