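test_that("model specifications validate their grids", {
  expect_error(model_spec("rf", mtry = 4), "mtry")
  expect_error(model_spec("rf", ntree = 550), "ntree")
  expect_error(model_spec("svm", cost = 3), "cost")
  expect_error(model_spec("ffnn", epochs = numeric(0)), "non-empty")
  expect_s3_class(model_spec("RF", ntree = c(500, 1000)), "model_spec")
})

test_that("single-class training data is rejected", {
  co <- fixture_cohort()[1:6, ]
  co$relapse <- 0L
  expect_error(tune_and_fit(model_spec("nb"), co), "both classes")
})

test_that("logistic regression recovers the generating coefficients", {
  cohort <- sample_cohort(default_config(), n = 5000, seed = 51)
  fit <- tune_and_fit(model_spec("lr"), cohort, seed = 51)
  est <- summary(fit$fit)$coefficients
  truth <- dlbcl_coefficients()
  for (i in seq_len(nrow(truth))) {
    term <- paste0(truth$feature[i], truth$level[i])
    expect_lt(abs(est[term, "Estimate"] - truth$coefficient[i]),
              3 * est[term, "Std. Error"])
  }
})

test_that("chosen hyperparameters come from the declared grids", {
  parts <- stratified_split(fixture_cohort(), seed = 52)
  rf <- tune_and_fit(model_spec("rf", ntree = c(500, 1000)), parts$train,
                     seed = 52)
  expect_true(rf$hyper$ntree %in% c(500, 1000))
  expect_true(rf$hyper$mtry %in% c(2, 3))
  svm <- tune_and_fit(model_spec("svm", cost = c(0.1, 1, 10),
                                 gamma = c(0.01, 0.1)), parts$train,
                      seed = 52)
  expect_true(svm$hyper$kernel %in% c("linear", "radial"))
  expect_true(svm$hyper$cost %in% c(0.1, 1, 10))
})

test_that("all scorers output probabilities in [0, 1] and keep OOF coverage", {
  parts <- stratified_split(fixture_cohort(), seed = 53)
  specs <- list(model_spec("nb"), model_spec("lr"),
                model_spec("rf", ntree = 500, mtry = 2),
                model_spec("svm", kernel = "linear", cost = 1),
                model_spec("ffnn", hidden = 25, epochs = 25))
  for (spec in specs) {
    fit <- tune_and_fit(spec, parts$train, seed = 53)
    sc <- predict_risk(fit, parts$test)
    expect_length(sc, nrow(parts$test))
    expect_true(all(sc >= 0 & sc <= 1))
    expect_equal(nrow(fit$oof), nrow(parts$train))
    expect_true(all(is.finite(fit$oof$score)))
    # prediction is deterministic given the fitted model
    expect_identical(sc, predict_risk(fit, parts$test))
  }
})

test_that("SVM min-max normalisation maps bounds to 0/1 and clips outside", {
  expect_equal(calibrisk:::minmax_scale(c(-2, 0, 2), -2, 2), c(0, 0.5, 1))
  expect_equal(calibrisk:::minmax_scale(3, -2, 2), 1)
  expect_equal(calibrisk:::minmax_scale(-7, -2, 2), 0)
  expect_equal(calibrisk:::minmax_scale(c(1, 5), 4, 4), c(0.5, 0.5))
})

test_that("unseen categories are reported with the offending feature", {
  parts <- stratified_split(fixture_cohort(), seed = 54)
  fit <- tune_and_fit(model_spec("nb"), parts$train, seed = 54)
  bad <- parts$test
  bad$sex <- as.character(bad$sex)
  bad$sex[3] <- "Unknown"
  expect_error(predict_risk(fit, bad), "sex")
})

test_that("LR screening keeps the causal variables and respects the OR identity", {
  cohort <- sample_cohort(default_config(), n = 20000, seed = 55)
  sel <- select_predictors_lr(cohort, alpha = 0.1)
  expect_true(all(dlbcl_predictors() %in% unique(sel$variable)))
  # at most a few noise variables clear a 0.1 screen by chance
  expect_lte(length(setdiff(unique(sel$variable), dlbcl_predictors())), 3)
  expect_equal(sel$odds_ratio, exp(sel$coefficient))
  full <- attr(sel, "full")
  expect_equal(nrow(full), sum(table(dlbcl_features()$feature) - 1))
})

test_that("null coefficients yield roughly nominal variable selection rates", {
  flat <- cohort_config(coefficients = dlbcl_coefficients()[0, ],
                        intercept = qlogis(0.35))
  hits <- 0; total <- 0
  for (r in 1:12) {
    co <- sample_cohort(flat, n = 800, seed = 600 + r)
    sel <- select_predictors_lr(co, alpha = 0.1)
    hits <- hits + length(unique(sel$variable))
    total <- total + length(unique(dlbcl_features()$feature))
  }
  # each of the 15 null variables should clear the screen ~10% of the time
  expect_gt(hits / total, 0.01)
  expect_lt(hits / total, 0.30)
})

test_that("forest importance separates causal signal from noise", {
  cohort <- sample_cohort(default_config(), n = 5000, seed = 56)
  imp <- rank_importance_rf(cohort, ntree = 300, seed = 56)
  expect_setequal(imp$feature, unique(dlbcl_features()$feature))
  noise <- c("age", "wbc", "ldh", "b2mg", "esr", "bcl6", "mum1", "ki67")
  for (top in c("stage", "ipi")) {
    expect_lt(imp$rank_accuracy[imp$feature == top],
              min(imp$rank_accuracy[imp$feature %in% noise]))
    expect_lt(imp$rank_gini[imp$feature == top],
              min(imp$rank_gini[imp$feature %in% noise]))
  }
})

test_that("a single informative feature tops both importance rankings", {
  set.seed(57)
  n <- 1500
  x <- tibble::tibble(
    signal = sample(c("A", "B"), n, replace = TRUE),
    blur1 = sample(c("A", "B"), n, replace = TRUE),
    blur2 = sample(c("X", "Y", "Z"), n, replace = TRUE)
  )
  x$relapse <- rbinom(n, 1, ifelse(x$signal == "A", 0.85, 0.15))
  imp <- rank_importance_rf(x, ntree = 300, seed = 57)
  expect_equal(imp$rank_accuracy[imp$feature == "signal"], 1)
  expect_equal(imp$rank_gini[imp$feature == "signal"], 1)
})
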