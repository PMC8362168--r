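test_that("argument contracts are enforced", {
  tb <- make_score_testbed(50, gamma = 2, seed = 1)
  expect_error(fit_rpr(tb, k = 0), ">= 1")
  expect_error(fit_rpr(tb, lambda = 0.5), "lambda")
  expect_error(fit_rpr(tb, grid_size = 1), "grid_size")
})

test_that("every fit satisfies monotonicity, endpoint bounds and the l1 budget", {
  set.seed(31)
  cases <- expand.grid(k = c(4, 12, 20), lambda = c(1, 16, 1024))
  tb <- make_score_testbed(800, gamma = 3, seed = 31)
  for (i in seq_len(nrow(cases))) {
    fit <- fit_rpr(tb, k = cases$k[i], lambda = cases$lambda[i])
    slack <- rpr_constraint_slack(fit)
    expect_gt(slack$min_derivative, -1e-8)
    expect_gt(slack$f_lo, -1e-8)
    expect_gt(slack$one_minus_f_hi, -1e-8)
    expect_gt(slack$l1_slack, -1e-8)
  }
})

test_that("perfectly calibrated data recovers the identity map", {
  tb <- make_score_testbed(5000, gamma = 1, seed = 32)
  fit <- fit_rpr(tb, k = 4, lambda = 4)
  g <- seq(0, 1, length.out = 101)
  expect_lt(max(abs(predict(fit, g) - g)), 0.02)
})

test_that("polynomial evaluation clamps to the domain and clips to [0, 1]", {
  ident <- structure(list(coefficients = c(0, 1), degree = 1L, lambda = 2,
                          s_lo = 0, s_hi = 1), class = "rpr_calibrator")
  expect_equal(predict(ident, 0.3), 0.3)
  expect_equal(predict(ident, c(-0.5, 1.5)), c(0, 1))  # endpoint values
  const <- structure(list(coefficients = c(0.7), degree = 1L, lambda = 1,
                          s_lo = 0, s_hi = 1), class = "rpr_calibrator")
  expect_equal(predict(const, c(0, 0.4, 1)), rep(0.7, 3))
  shifted <- structure(list(coefficients = c(0.25, 0.5), degree = 1L,
                            lambda = 1, s_lo = 0.2, s_hi = 0.8),
                       class = "rpr_calibrator")
  expect_equal(predict(shifted, 0.1), predict(shifted, 0.2))  # clamped low
})

test_that("the QP optimum beats random feasible polynomials", {
  tb <- make_score_testbed(300, gamma = 2, seed = 33)
  k <- 4; lambda <- 4
  fit <- fit_rpr(tb, k = k, lambda = lambda)
  S <- outer(tb$score, 0:k, `^`)
  obj <- function(a) mean((drop(S %*% a) - tb$label)^2)
  expect_equal(fit$objective, obj(fit$coefficients), tolerance = 1e-12)
  g <- seq(0, 1, length.out = 401)
  set.seed(33)
  feasible_best <- Inf
  tries <- 0
  while (tries < 1000) {
    tries <- tries + 1
    a <- runif(k + 1, -1, 1)
    a <- a / sum(abs(a)) * runif(1, 0, lambda)
    dp <- a[-1] * seq_len(k)
    ok <- min(calibrisk:::eval_poly(dp, g)) >= 0 &&
      calibrisk:::eval_poly(a, 0) >= 0 && calibrisk:::eval_poly(a, 1) <= 1
    if (ok) feasible_best <- min(feasible_best, obj(a))
  }
  expect_lte(fit$objective, feasible_best + 1e-10)
})

test_that("calibration error decreases with calibration-set size", {
  med_ece <- vapply(c(200, 2000, 20000), function(n) {
    eces <- vapply(1:5, function(r) {
      tb <- make_score_testbed(n, gamma = 3, seed = 100 * r + n)
      fit <- fit_rpr(tb, k = 8, lambda = 16)
      holdout <- make_score_testbed(4000, gamma = 3, seed = 999 + r)
      cal <- data.frame(score = predict(fit, holdout$score),
                        label = holdout$label)
      ece(bin_equal_size(cal))
    }, numeric(1))
    median(eces)
  }, numeric(1))
  expect_lt(med_ece[2], med_ece[1])
  expect_lt(med_ece[3], med_ece[1])
})

test_that("hyperparameter search stays on the grid and is reproducible", {
  tb <- make_score_testbed(400, gamma = 2, seed = 34)
  sel <- select_rpr_hyperparams(tb, k_grid = c(4, 6, 8),
                                lambda_grid = c(1, 4, 16), seed = 5)
  expect_true(sel$k %in% c(4, 6, 8))
  expect_true(sel$lambda %in% c(1, 4, 16))
  sel2 <- select_rpr_hyperparams(tb, k_grid = c(4, 6, 8),
                                 lambda_grid = c(1, 4, 16), seed = 5)
  expect_identical(sel, sel2)
  expect_error(select_rpr_hyperparams(tb, k_grid = integer(0)), "non-empty")
})

test_that("a linear true map needs no high-degree polynomial", {
  tb <- make_score_testbed(4000, gamma = 1, seed = 35)
  sel <- select_rpr_hyperparams(tb, k_grid = c(4, 8, 12, 16, 20),
                                lambda_grid = c(1, 4), seed = 6)
  expect_lte(sel$k, 8)
})
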