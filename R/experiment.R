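# Repeated stratified hold-out protocol: per repetition, split 2:1, tune
# and fit each base model with 3-fold CV, train the three calibrators on
# the model's own out-of-fold predictions, and evaluate all raw and
# calibrated score vectors on the held-out third.

#' Configuration of the repeated hold-out experiment
#'
#' Defaults follow the full study protocol: 500 stratified 2/3 hold-out
#' repetitions, 3-fold cross-validation for hyperparameters and out-of-fold
#' calibration sets, 10 calibration bins, a 0.05 well-calibration cut on
#' the Hosmer-Lemeshow p-value, and prediction-histogram cut points at
#' 0.1, 0.2, ..., 1.  Scaled-down runs shrink `n_repetitions`, the model
#' grids and the RPR grids; the shape of the protocol is unchanged.
#'
#' @param n_repetitions Number of hold-out repetitions (default 500).
#' @param train_fraction Training proportion of each split (default 2/3).
#' @param cv_folds Folds for hyperparameter tuning and out-of-fold
#'   calibration predictions (default 3).
#' @param bins Number of equal-size calibration bins (default 10).
#' @param hl_alpha Well-calibration threshold on the H-L p-value.
#' @param cut_points Right edges of the prediction-histogram intervals.
#' @param families Base-model families to run.
#' @param specs Optional named list of [model_spec()] overrides per family.
#' @param rpr_k_grid,rpr_lambda_grid RPR hyperparameter grids (defaults
#'   4..20 and `4^(0:5)`).
#' @return An object of class `experiment_config`.
#' @export
#' @examples
#' experiment_config(n_repetitions = 20, families = c("nb", "lr"))
experiment_config <- function(n_repetitions = 500, train_fraction = 2 / 3,
                              cv_folds = 3, bins = 10, hl_alpha = 0.05,
                              cut_points = seq(0.1, 1, by = 0.1),
                              families = c("nb", "lr", "rf", "svm", "ffnn"),
                              specs = list(),
                              rpr_k_grid = 4:20,
                              rpr_lambda_grid = 4^(0:5)) {
  if (n_repetitions < 1) abort("`n_repetitions` must be at least 1.")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1.")
  }
  if (any(diff(cut_points) <= 0) || any(cut_points <= 0) ||
      any(cut_points > 1)) {
    abort("`cut_points` must be strictly increasing in (0, 1].")
  }
  families <- match.arg(tolower(families),
                        c("nb", "lr", "rf", "svm", "ffnn"),
                        several.ok = TRUE)
  full <- setNames(lapply(families, model_spec), families)
  for (f in names(specs)) {
    stopifnot(inherits(specs[[f]], "model_spec"))
    full[[tolower(f)]] <- specs[[f]]
  }
  structure(list(n_repetitions = n_repetitions,
                 train_fraction = train_fraction, cv_folds = cv_folds,
                 bins = bins, hl_alpha = hl_alpha, cut_points = cut_points,
                 families = families, specs = full[families],
                 rpr_k_grid = rpr_k_grid,
                 rpr_lambda_grid = rpr_lambda_grid),
            class = "experiment_config")
}

#' Stratified hold-out split
#'
#' Splits a cohort into training and test sets, sampling
#' `round(fraction * n)` rows within each outcome stratum for training and
#' leaving the remainder to test, so the class ratio is preserved up to
#' rounding.  A 510-row cohort with 181 events at fraction 2/3 yields
#' exactly 340 training (121 events) and 170 test rows.
#'
#' @param data Cohort with a 0/1 outcome column.
#' @param fraction Training proportion (default 2/3).
#' @param seed Optional integer seed.
#' @param label Outcome column name.
#' @return A list with elements `train` and `test`.
#' @export
stratified_split <- function(data, fraction = 2 / 3, seed = NULL,
                             label = "relapse") {
  y <- data[[label]]
  if (is.null(y)) abort(paste0("No outcome column `", label, "`."))
  strata <- unique(y)
  if (length(strata) < 2) abort("Both classes must be present to stratify.")
  if (!is.null(seed)) withr::local_seed(seed)
  tr_idx <- unlist(lapply(strata, function(cls) {
    idx <- which(y == cls)
    if (length(idx) < 2) {
      abort("Every outcome stratum needs at least 2 rows.")
    }
    sample(idx, round(fraction * length(idx)))
  }))
  if (length(tr_idx) >= nrow(data)) {
    abort("`fraction` leaves an empty test set.")
  }
  list(train = data[sort(tr_idx), , drop = FALSE],
       test = data[-sort(tr_idx), , drop = FALSE])
}

#' Out-of-fold predictions of a base model
#'
#' Tunes the model on `data` and returns the validation-fold predictions of
#' the selected configuration under stratified `folds`-fold
#' cross-validation: each row receives exactly one prediction, made by a
#' model that never saw it.  This is the leakage-free training set for the
#' probability calibrators.
#'
#' @inheritParams tune_and_fit
#' @return A tibble with columns `score` and `label`, one row per row of
#'   `data`.
#' @export
out_of_fold_scores <- function(spec, data, features = dlbcl_predictors(),
                               label = "relapse", folds = 3, seed = NULL) {
  fit <- tune_and_fit(spec, data, features = features, label = label,
                      folds = folds, seed = seed)
  fit$oof
}

interval_counts <- function(scores, cut_points) {
  edges <- c(0, cut_points)
  i <- findInterval(scores, edges, rightmost.closed = TRUE)
  i[i < 1L] <- 1L
  i[i > length(cut_points)] <- length(cut_points)
  tabulate(i, nbins = length(cut_points))
}

#' Run one hold-out repetition
#'
#' One pass of the full protocol on a fixed cohort: stratified split; per
#' base family, hyperparameter tuning by stratified CV, refit on the full
#' training set and prediction of the test set; per family, Platt,
#' isotonic (PAV) and RPR calibrators trained on that family's out-of-fold
#' predictions (RPR hyperparameters by CV on the calibration set) and
#' applied to the test predictions; and evaluation of every raw and
#' calibrated score vector.
#'
#' @param data The cohort (one row per patient).
#' @param config An [experiment_config()].
#' @param rep_seed Integer seed for this repetition; the same cohort and
#'   seed reproduce the records exactly.
#' @return A list with `records` (one row per model x calibration:
#'   metrics from [evaluate_scores()]) and `histogram` (per model x
#'   calibration counts of test predictions per probability interval).
#' @export
run_repetition <- function(data, config, rep_seed) {
  stopifnot(inherits(config, "experiment_config"))
  parts <- stratified_split(data, config$train_fraction, seed = rep_seed)
  test_labels <- as.numeric(parts$test$relapse)
  records <- list()
  hist_rows <- list()
  for (j in seq_along(config$families)) {
    fam <- config$families[j]
    fit <- tune_and_fit(config$specs[[fam]], parts$train,
                        folds = config$cv_folds,
                        seed = rep_seed + 10000L * j)
    raw <- predict_risk(fit, parts$test)
    cal_set <- fit$oof
    maps <- list(
      raw = NULL,
      platt = fit_platt(cal_set),
      isoreg = fit_isotonic_pav(cal_set),
      rpr = {
        hp <- select_rpr_hyperparams(cal_set, k_grid = config$rpr_k_grid,
                                     lambda_grid = config$rpr_lambda_grid,
                                     folds = config$cv_folds,
                                     seed = rep_seed + 10000L * j + 1L)
        fit_rpr(cal_set, k = hp$k, lambda = hp$lambda)
      }
    )
    for (cal in names(maps)) {
      sc <- if (cal == "raw") raw else predict(maps[[cal]], raw)
      rec <- .evaluate_scores(sc, test_labels, k = config$bins)
      rec$model <- toupper(fam)
      rec$calibration <- cal
      records[[length(records) + 1L]] <- rec
      hist_rows[[length(hist_rows) + 1L]] <- tibble::tibble(
        model = toupper(fam), calibration = cal,
        interval = seq_along(config$cut_points),
        upper = config$cut_points,
        count = interval_counts(sc, config$cut_points)
      )
    }
  }
  list(
    records = dplyr::relocate(purrr::list_rbind(records), "model",
                              "calibration"),
    histogram = purrr::list_rbind(hist_rows)
  )
}

#' Run the repeated hold-out experiment
#'
#' Repeats [run_repetition()] `config$n_repetitions` times with
#' per-repetition seeds `seed + 1, ..., seed + n`, collecting the
#' evaluation records and prediction histograms of every repetition.
#'
#' @inheritParams run_repetition
#' @param seed Master seed; repetition seeds are derived from it, so a
#'   fixed seed reproduces the whole experiment.
#' @return An object of class `calibration_experiment`: a list with
#'   `records` (tibble, one row per repetition x model x calibration),
#'   `histogram`, `config`, `seed` and `rep_seeds`.  [tidy()] aggregates
#'   it into the median / quartile summary table.
#' @export
#' @examples
#' \donttest{
#' cohort <- sample_cohort(dlbcl_cohort_config(), n = 510, seed = 7)
#' cfg <- experiment_config(n_repetitions = 3, families = c("nb", "lr"),
#'                          rpr_k_grid = c(4, 6), rpr_lambda_grid = c(1, 4))
#' exp <- run_experiment(cohort, cfg, seed = 1)
#' tidy(exp)
#' }
run_experiment <- function(data, config = experiment_config(), seed = 1) {
  stopifnot(inherits(config, "experiment_config"))
  rep_seeds <- seed + seq_len(config$n_repetitions)
  out <- vector("list", config$n_repetitions)
  for (r in seq_len(config$n_repetitions)) {
    out[[r]] <- tryCatch(
      run_repetition(data, config, rep_seed = rep_seeds[r]),
      error = function(e) {
        abort(paste0("Repetition ", r, " (seed ", rep_seeds[r],
                     ") failed: ", conditionMessage(e)))
      })
  }
  records <- purrr::imap(out, function(o, r) {
    o$records$repetition <- r
    o$records
  }) |> purrr::list_rbind()
  histogram <- purrr::imap(out, function(o, r) {
    o$histogram$repetition <- r
    o$histogram
  }) |> purrr::list_rbind()
  structure(list(records = dplyr::relocate(records, "repetition"),
                 histogram = dplyr::relocate(histogram, "repetition"),
                 config = config, seed = seed, rep_seeds = rep_seeds),
            class = "calibration_experiment")
}

#' @export
print.calibration_experiment <- function(x, ...) {
  cat(sprintf("<calibration_experiment>  %d repetitions x %d models\n",
              x$config$n_repetitions,
              length(unique(paste(x$records$model, x$records$calibration)))))
  invisible(x)
}

q_fmt <- function(x, digits = 3) {
  q <- quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE)
  sprintf("%.*f (%.*f-%.*f)", digits, q[1], digits, q[2], digits, q[3])
}

#' Aggregate an experiment into the median / quartile summary table
#'
#' Per model and calibration method: the median, 25th and 75th percentile
#' (linear interpolation) of AUC, ECE, MCE and Brier score over the
#' repetitions, the median H-L p-value, and the number of repetitions in
#' which the model was well-calibrated (H-L p above `alpha`; repetitions
#' where the test was undefined count as not well-calibrated).
#'
#' @param x A [run_experiment()] result.
#' @param alpha Well-calibration threshold (defaults to the experiment's).
#' @param ... Unused.
#' @return A tibble with one row per model x calibration.
#' @exportS3Method generics::tidy
tidy.calibration_experiment <- function(x, alpha = x$config$hl_alpha, ...) {
  qs <- function(v, p) quantile(v, p, na.rm = TRUE, names = FALSE)
  x$records |>
    dplyr::group_by(.data$model, .data$calibration) |>
    dplyr::summarise(
      dplyr::across(c("auc", "ece", "mce", "brier"),
                    list(median = ~ qs(.x, 0.5), p25 = ~ qs(.x, 0.25),
                         p75 = ~ qs(.x, 0.75))),
      hl_p_median = qs(.data$hl_p, 0.5),
      n_well_calibrated = sum(!is.na(.data$hl_p) & .data$hl_p > alpha),
      n_repetitions = dplyr::n(),
      .groups = "drop"
    )
}

#' @exportS3Method generics::glance
glance.calibration_experiment <- function(x, ...) {
  tibble::tibble(n_repetitions = x$config$n_repetitions,
                 n_models = length(unique(paste(x$records$model,
                                                x$records$calibration))),
                 train_fraction = x$config$train_fraction,
                 bins = x$config$bins, seed = x$seed)
}

#' Count well-calibrated repetitions per model
#'
#' A model counts as well-calibrated in a repetition when its
#' Hosmer-Lemeshow p-value exceeds `alpha`; repetitions with an undefined
#' test (missing p) count as not well-calibrated.
#'
#' @param records The `records` tibble of a [run_experiment()] result (or
#'   the result itself).
#' @param alpha Threshold on the H-L p-value (default 0.05).
#' @return A tibble with `model`, `calibration`, `n_well_calibrated`,
#'   `n_repetitions`.
#' @export
count_well_calibrated <- function(records, alpha = 0.05) {
  if (inherits(records, "calibration_experiment")) records <- records$records
  records |>
    dplyr::group_by(.data$model, .data$calibration) |>
    dplyr::summarise(
      n_well_calibrated = sum(!is.na(.data$hl_p) & .data$hl_p > alpha),
      n_repetitions = dplyr::n(), .groups = "drop")
}

#' Median prediction counts per probability interval
#'
#' Groups test-set predictions into the fixed intervals
#' `[0, 0.1), [0.1, 0.2), ..., [0.9, 1]` (or the configured cut points)
#' within each repetition and reports the median count per interval over
#' repetitions, per model and calibration method.
#'
#' @param x A [run_experiment()] result (or its `histogram` tibble).
#' @return A tibble with `model`, `calibration`, `interval`, `upper`,
#'   `median_count`.
#' @export
prediction_histogram <- function(x) {
  h <- if (inherits(x, "calibration_experiment")) x$histogram else x
  h |>
    dplyr::group_by(.data$model, .data$calibration, .data$interval,
                    .data$upper) |>
    dplyr::summarise(median_count = stats::median(.data$count),
                     .groups = "drop")
}
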