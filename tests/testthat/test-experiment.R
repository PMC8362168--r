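test_that("stratified splitting reproduces the 340/170 arithmetic", {
  cohort <- tibble::tibble(
    sex = factor(rep(c("Male", "Female"), 255)),
    relapse = rep(c(1L, 0L), c(181, 329))
  )
  parts <- stratified_split(cohort, fraction = 2 / 3, seed = 1)
  expect_equal(nrow(parts$train), 340)
  expect_equal(nrow(parts$test), 170)
  expect_equal(sum(parts$train$relapse), 121)
  expect_equal(sum(parts$test$relapse), 60)
})

test_that("splitting validates its inputs and boundary fractions", {
  cohort <- fixture_cohort()
  expect_error(stratified_split(cohort, fraction = 0.999), "empty test")
  one_class <- cohort
  one_class$relapse <- 1L
  expect_error(stratified_split(one_class), "Both classes")
  # train class ratio within one unit per stratum of the cohort ratio
  parts <- stratified_split(cohort, seed = 2)
  expect_lt(abs(mean(parts$train$relapse) - mean(cohort$relapse)),
            2 / min(table(cohort$relapse)))
  # reproducible given the seed
  parts2 <- stratified_split(cohort, seed = 2)
  expect_identical(parts, parts2)
})

test_that("out-of-fold predictions cover each training row exactly once", {
  parts <- stratified_split(fixture_cohort(), seed = 3)
  oof <- out_of_fold_scores(model_spec("nb"), parts$train, seed = 3)
  expect_equal(nrow(oof), nrow(parts$train))
  expect_true(all(is.finite(oof$score)))
  expect_equal(oof$label, as.numeric(parts$train$relapse))
  oof2 <- out_of_fold_scores(model_spec("nb"), parts$train, seed = 3)
  expect_identical(oof, oof2)
})

test_that("a repetition yields one record per model and calibration and is deterministic", {
  cfg <- scaled_experiment_config(1, families = c("nb", "lr"))
  rep1 <- run_repetition(fixture_cohort(), cfg, rep_seed = 5)
  expect_equal(nrow(rep1$records), 8)
  expect_setequal(rep1$records$calibration,
                  c("raw", "platt", "isoreg", "rpr"))
  rep2 <- run_repetition(fixture_cohort(), cfg, rep_seed = 5)
  expect_identical(rep1, rep2)
  # strictly monotone calibrators leave the AUC untouched
  w <- tidyr::pivot_wider(rep1$records[, c("model", "calibration", "auc")],
                          names_from = "calibration", values_from = "auc")
  expect_equal(w$platt, w$raw, tolerance = 1e-13)
  expect_equal(w$rpr, w$raw, tolerance = 1e-13)
})

test_that("experiment aggregation collapses correctly for one repetition", {
  cfg <- scaled_experiment_config(1, families = "nb")
  exp1 <- run_experiment(fixture_cohort(), cfg, seed = 6)
  agg <- tidy(exp1)
  expect_equal(agg$ece_median, agg$ece_p25)
  expect_equal(agg$ece_median, agg$ece_p75)
  expect_equal(unique(agg$n_repetitions), 1L)
})

test_that("experiments are reproducible by seed and sensitive to it", {
  cfg <- scaled_experiment_config(2, families = "nb")
  e1 <- run_experiment(fixture_cohort(), cfg, seed = 7)
  e2 <- run_experiment(fixture_cohort(), cfg, seed = 7)
  e3 <- run_experiment(fixture_cohort(), cfg, seed = 8)
  expect_identical(e1$records, e2$records)
  expect_false(identical(e1$records, e3$records))
})

test_that("well-calibrated counting thresholds the H-L p-values", {
  rec <- tibble::tibble(model = "NB", calibration = "raw",
                        hl_p = c(1, 1, 0.01, NA))
  out <- count_well_calibrated(rec, alpha = 0.05)
  expect_equal(out$n_well_calibrated, 2L)   # NA counts as not calibrated
  expect_equal(out$n_repetitions, 4L)
  rec$hl_p <- rep(0.01, 4)
  expect_equal(count_well_calibrated(rec)$n_well_calibrated, 0L)
})

test_that("prediction histograms partition the test set", {
  cuts <- seq(0.1, 1, by = 0.1)
  expect_equal(calibrisk:::interval_counts(rep(0.15, 170), cuts),
               c(0, 170, rep(0, 8)))
  set.seed(9)
  s <- runif(5000)
  counts <- calibrisk:::interval_counts(s, cuts)
  expect_equal(sum(counts), 5000)
  expect_true(all(abs(counts - 500) < 5 * sqrt(500)))
  # boundary scores land in the defined intervals
  expect_equal(calibrisk:::interval_counts(c(0, 0.1, 1), cuts),
               c(1, 1, rep(0, 7), 1))
})

test_that("experiment records support the summary writer downstream", {
  cfg <- scaled_experiment_config(2, families = "nb")
  ex <- run_experiment(fixture_cohort(), cfg, seed = 10)
  h <- prediction_histogram(ex)
  sums <- tapply(ex$histogram$count,
                 paste(ex$histogram$repetition, ex$histogram$model,
                       ex$histogram$calibration), sum)
  expect_true(all(sums == 170))
  expect_true(all(h$median_count >= 0))
  g <- glance(ex)
  expect_equal(g$n_repetitions, 2)
})
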