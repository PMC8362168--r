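toy_bins <- function() {
  bin_equal_size(data.frame(score = c(0.2, 0.2, 0.8, 0.8),
                            label = c(0, 1, 1, 1)), k = 2)
}

test_that("AUC handles perfect ranking, ties and hand-counted pairs", {
  expect_equal(auc(data.frame(score = 1:10 / 10,
                              label = rep(c(0, 1), each = 5))), 1)
  expect_equal(auc(data.frame(score = c(0.1, 0.4, 0.35, 0.8),
                              label = c(0, 0, 1, 1))), 0.75)
  expect_equal(auc(data.frame(score = rep(0.3, 8),
                              label = rep(c(0, 1), 4))), 0.5)
  expect_error(auc(data.frame(score = c(.1, .2), label = c(1, 1))),
               "one class")
})

test_that("AUC is rank-invariant and agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  s <- runif(200)
  y <- rbinom(200, 1, s)
  d <- data.frame(score = s, label = y)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc(d), ref, tolerance = 1e-12)
  for (g in list(function(x) x^3, function(x) plogis(5 * x), exp)) {
    expect_equal(auc(data.frame(score = g(s), label = y)), auc(d),
                 tolerance = 1e-12)
  }
})

test_that("equal-size binning splits sorted scores into near-equal bins", {
  b <- toy_bins()
  expect_s3_class(b, "calibration_bins")
  expect_equal(b$p_mean, c(0.2, 0.8))
  expect_equal(b$o_rate, c(0.5, 1.0))
  expect_equal(b$exp_pos, c(0.4, 1.6))
  expect_equal(b$obs_pos, c(1, 2))

  d <- data.frame(score = runif(10), label = rbinom(10, 1, 0.5))
  b10 <- bin_equal_size(d, k = 10)
  expect_true(all(b10$n == 1))
  expect_true(all(b10$o_rate %in% c(0, 1)))
  expect_error(bin_equal_size(d, k = 11), "at least")

  # sizes differ by at most one and sum to n
  d2 <- data.frame(score = runif(103), label = rbinom(103, 1, 0.5))
  b7 <- bin_equal_size(d2, k = 7)
  expect_equal(sum(b7$n), 103)
  expect_lte(diff(range(b7$n)), 1)
  expect_true(!is.unsorted(b7$p_mean))
})

test_that("Hosmer-Lemeshow matches its defining formula and degrees of freedom", {
  # perfectly matching observed and expected counts in every cell
  perfect <- data.frame(score = rep(0.25, 12),
                        label = rep(c(1, 0, 0, 0), 3))
  hl <- hosmer_lemeshow(bin_equal_size(perfect, k = 3))
  expect_equal(hl$statistic, 0)
  expect_equal(hl$df, 1L)
  expect_equal(hl$p_value, 1)

  # two bins leave df = 0: statistic defined, test not
  b <- toy_bins()
  expect_equal(as.numeric(hl_statistic(b)),
               (1 - 0.4)^2 / 0.4 + (1 - 1.6)^2 / 1.6 +
                 (2 - 1.6)^2 / 1.6 + (0 - 0.4)^2 / 0.4)
  expect_error(hosmer_lemeshow(b), "at least 3 bins")

  # degenerate bins (expected counts ~ 0) are merged before dividing
  d <- data.frame(score = c(rep(0, 4), rep(0.5, 8)),
                  label = c(rep(0, 4), rep(c(0, 1), 4)))
  expect_silent(stat <- hl_statistic(bin_equal_size(d, k = 3)))
  expect_true(is.finite(stat))
  expect_lt(attr(stat, "k_effective"), 3)
})

test_that("ECE and MCE are the mean and max bin gaps in percentage points", {
  b <- toy_bins()
  expect_equal(ece(b), 25)
  expect_equal(mce(b), 30)
  expect_gte(mce(b), ece(b))

  # perfectly calibrated bins
  perfect <- data.frame(score = rep(0.5, 10), label = rep(c(0, 1), 5))
  bp <- bin_equal_size(perfect, k = 1)
  expect_equal(ece(bp), 0)
  expect_equal(mce(bp), 0)

  # single bin: 100 x |mean prediction - overall rate|
  one <- bin_equal_size(data.frame(score = rep(0.3, 10),
                                   label = rep(c(1, 0), c(6, 4))), k = 1)
  expect_equal(ece(one), 100 * abs(0.3 - 0.6))
})

test_that("Brier score is the mean squared error of the probabilities", {
  expect_equal(brier(data.frame(score = c(0, 1, 1), label = c(0, 1, 1))), 0)
  expect_equal(brier(data.frame(score = rep(0.5, 6),
                                label = rep(c(0, 1), 3))), 0.25)
  expect_equal(brier(data.frame(score = c(0.2, 0.8), label = c(0, 1))), 0.04)
})

test_that("evaluate_scores bundles all metrics and degrades gracefully", {
  tb <- make_score_testbed(400, gamma = 2, seed = 8)
  rec <- evaluate_scores(tb)
  expect_named(rec, c("auc", "ece", "mce", "brier", "hl_statistic",
                      "hl_df", "hl_p"))
  expect_equal(rec$auc, auc(tb))
  expect_gte(rec$mce, rec$ece)
  # too few effective bins for the H-L test: NA columns, no error
  tiny <- data.frame(score = c(.2, .4, .6, .8), label = c(0, 0, 1, 1))
  rec2 <- evaluate_scores(tiny, k = 2)
  expect_true(is.na(rec2$hl_p))
  expect_false(is.na(rec2$auc))
})
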