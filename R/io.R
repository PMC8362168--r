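# CSV readers/writers, calibrator serialization and the run manifest.

#' Apply a fitted calibration map to scores
#'
#' Generic convenience wrapper: dispatches to the `predict()` method of any
#' fitted calibrator (`platt_calibrator`, `isotonic_calibrator`,
#' `rpr_calibrator`).
#'
#' @param object A fitted calibrator.
#' @param scores Numeric scores in `[0, 1]`.
#' @return Calibrated probabilities.
#' @export
calibrate_scores <- function(object, scores) {
  predict(object, scores)
}

#' Write / read a cohort as CSV
#'
#' `write_cohort()` stores a cohort with one column per feature (category
#' labels as plain strings), the 0/1 outcome column and, when present, the
#' generator's `true_risk` column.  `read_cohort()` reads it back and
#' validates every cell against the feature vocabulary, case-sensitively;
#' unknown categories and missing columns are schema errors naming the row
#' and column, extra columns are kept with a warning.
#'
#' @param data Cohort tibble.
#' @param path File path.
#' @param features Vocabulary tibble (`feature`, `level`, ...); defaults to
#'   [dlbcl_features()].
#' @param label Outcome column name.
#' @return `read_cohort()` returns the validated cohort with feature
#'   columns as factors in vocabulary order; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, features = dlbcl_features(),
                        label = "relapse") {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0 && ncol(raw) == 0) abort("Cohort file is empty.")
  feat_names <- unique(features$feature)
  missing_cols <- setdiff(c(feat_names, label), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(raw), c(feat_names, label, "true_risk"))
  if (length(extra) > 0) {
    warn(paste0("Ignoring unrecognised column(s): ",
                paste(extra, collapse = ", ")))
  }
  out <- raw
  for (f in feat_names) {
    lev <- features$level[features$feature == f]
    bad <- which(!raw[[f]] %in% lev)
    if (length(bad) > 0) {
      abort(paste0("Unknown category \"", raw[[f]][bad[1]],
                   "\" in column `", f, "`, row ", bad[1], "."))
    }
    out[[f]] <- factor(raw[[f]], levels = lev)
  }
  y <- raw[[label]]
  if (!all(y %in% c("0", "1"))) {
    abort(paste0("Column `", label, "` must be 0/1."))
  }
  out[[label]] <- as.integer(y)
  if ("true_risk" %in% names(raw)) {
    out$true_risk <- as.numeric(raw$true_risk)
  }
  out
}

#' Serialize a fitted calibration map to plain text
#'
#' Writes any fitted calibrator as a small JSON record
#' (`{"method": "platt" | "isotonic" | "rpr", ...}`) with full-precision
#' numbers, and reads it back into an object of the same class.
#' Round-trips are exact.
#'
#' @param object A fitted calibrator.
#' @param path File path.
#' @return `read_calibrator()` returns the reconstructed calibrator;
#'   `write_calibrator()` returns `path` invisibly.
#' @export
write_calibrator <- function(object, path) {
  rec <- if (inherits(object, "platt_calibrator")) {
    list(method = "platt", A = object$A, B = object$B,
         n_pos = object$n_pos, n_neg = object$n_neg)
  } else if (inherits(object, "isotonic_calibrator")) {
    list(method = "isotonic", score_min = object$blocks$score_min,
         score_max = object$blocks$score_max, level = object$blocks$level,
         n_block = object$blocks$n, n = object$n)
  } else if (inherits(object, "rpr_calibrator")) {
    list(method = "rpr", coefficients = object$coefficients,
         degree = object$degree, lambda = object$lambda,
         s_lo = object$s_lo, s_hi = object$s_hi, n = object$n)
  } else {
    abort("Not a fitted calibrator.")
  }
  jsonlite::write_json(rec, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_calibrator
#' @export
read_calibrator <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(rec$method,
    platt = structure(list(A = rec$A, B = rec$B, loss = NA_real_,
                           iterations = NA_integer_, converged = TRUE,
                           n_pos = rec$n_pos, n_neg = rec$n_neg),
                      class = "platt_calibrator"),
    isotonic = structure(
      list(blocks = tibble::tibble(score_min = rec$score_min,
                                   score_max = rec$score_max,
                                   level = rec$level, n = rec$n_block),
           n = rec$n),
      class = "isotonic_calibrator"),
    rpr = structure(list(coefficients = rec$coefficients,
                         degree = as.integer(rec$degree),
                         lambda = rec$lambda, s_lo = rec$s_lo,
                         s_hi = rec$s_hi, grid_size = NA_integer_,
                         objective = NA_real_, refinements = NA_integer_,
                         n = rec$n),
                    class = "rpr_calibrator"),
    abort(paste0("Unknown calibrator method: ", rec$method))
  )
}

#' Write experiment results, summaries and a run manifest
#'
#' Writes into `dir`: `summary.csv` (the [tidy()] aggregate plus formatted
#' `median (P25-P75)` columns), `records.csv` (raw per-repetition
#' metrics), `well_calibrated.csv`, `histogram.csv` (median prediction
#' counts per interval) and `manifest.json` (package version, master and
#' per-repetition seeds, configuration snapshot, timestamp).  The CSV
#' outputs are a pure function of the experiment object, so re-running the
#' writer reproduces them byte for byte.
#'
#' @param x A [run_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return The paths of the written files, invisibly.
#' @export
write_experiment_results <- function(x, dir) {
  stopifnot(inherits(x, "calibration_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  agg <- tidy(x)
  pretty <- x$records |>
    dplyr::group_by(.data$model, .data$calibration) |>
    dplyr::summarise(AUC = q_fmt(.data$auc), ECE = q_fmt(.data$ece),
                     MCE = q_fmt(.data$mce), BS = q_fmt(.data$brier),
                     P_value = q_fmt(.data$hl_p), .groups = "drop")
  paths <- c(summary = file.path(dir, "summary.csv"),
             records = file.path(dir, "records.csv"),
             well_calibrated = file.path(dir, "well_calibrated.csv"),
             histogram = file.path(dir, "histogram.csv"),
             manifest = file.path(dir, "manifest.json"))
  readr::write_csv(dplyr::left_join(pretty, agg,
                                    by = c("model", "calibration")),
                   paths["summary"])
  readr::write_csv(x$records, paths["records"])
  readr::write_csv(count_well_calibrated(x, alpha = x$config$hl_alpha),
                   paths["well_calibrated"])
  readr::write_csv(prediction_histogram(x), paths["histogram"])
  cfg <- x$config
  manifest <- list(
    package = "calibrisk",
    version = as.character(utils::packageVersion("calibrisk")),
    written = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = x$seed,
    rep_seeds = x$rep_seeds,
    config = list(n_repetitions = cfg$n_repetitions,
                  train_fraction = cfg$train_fraction,
                  cv_folds = cfg$cv_folds, bins = cfg$bins,
                  hl_alpha = cfg$hl_alpha, cut_points = cfg$cut_points,
                  families = cfg$families,
                  rpr_k_grid = cfg$rpr_k_grid,
                  rpr_lambda_grid = cfg$rpr_lambda_grid)
  )
  jsonlite::write_json(manifest, paths["manifest"], digits = I(17),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
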