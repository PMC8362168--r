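#' Configuration of the synthetic cohort generator
#'
#' Bundles everything the generator needs: per-feature category marginals,
#' the log-odds coefficients of the true outcome model, the model intercept
#' and the target marginal event rate.  Defaults emulate the reference DLBCL
#' cohort: 15 independent categorical features with the empirical marginals
#' of [dlbcl_features()] and a logistic outcome driven by the seven
#' predictors of [dlbcl_coefficients()].
#'
#' The intercept may be left `NULL` and solved afterwards with
#' [solve_intercept()] so that the expected event rate matches
#' `target_event_rate`; [sample_cohort()] refuses to run with an unset
#' intercept.  [dlbcl_cohort_config()] returns the default configuration
#' with the intercept already solved.
#'
#' @param features Tibble with columns `feature`, `level`, `prob` and
#'   (optionally) `reference`, as returned by [dlbcl_features()].  Within
#'   each feature, `prob` must be nonnegative and sum to 1 (tolerance
#'   1e-12).
#' @param coefficients Tibble with columns `feature`, `level`,
#'   `coefficient`: the log-odds of each non-reference level.  Every
#'   (`feature`, `level`) pair must exist in `features` and must not be a
#'   reference level.
#' @param intercept Log-odds intercept of the outcome model, or `NULL` (to
#'   be solved).
#' @param target_event_rate Marginal event proportion the intercept should
#'   reproduce; default 181/510.
#' @return An object of class `cohort_config`.
#' @seealso [solve_intercept()], [sample_cohort()]
#' @export
#' @examples
#' cfg <- cohort_config()
#' cfg$intercept <- solve_intercept(cfg)
cohort_config <- function(features = dlbcl_features(),
                          coefficients = dlbcl_coefficients(),
                          intercept = NULL,
                          target_event_rate = 181 / 510) {
  stopifnot(is.data.frame(features),
            all(c("feature", "level", "prob") %in% names(features)),
            is.data.frame(coefficients),
            all(c("feature", "level", "coefficient") %in% names(coefficients)))
  if (!is.null(intercept) && (!is.numeric(intercept) || !is.finite(intercept))) {
    abort("`intercept` must be a finite number or NULL.")
  }
  if (!is.numeric(target_event_rate) || target_event_rate <= 0 ||
      target_event_rate >= 1) {
    abort("`target_event_rate` must lie strictly between 0 and 1.")
  }
  if (any(features$prob < 0)) {
    abort("Marginal probabilities must be nonnegative.")
  }
  sums <- tapply(features$prob, features$feature, sum)
  if (any(abs(sums - 1) > 1e-12)) {
    bad <- names(sums)[abs(sums - 1) > 1e-12]
    abort(paste0("Marginal probabilities of ", paste(bad, collapse = ", "),
                 " do not sum to 1."))
  }
  if (!"reference" %in% names(features)) {
    features$reference <- !duplicated(features$feature)
  }
  key <- function(d) paste(d$feature, d$level, sep = "\r")
  miss <- !key(coefficients) %in% key(features)
  if (any(miss)) {
    abort(paste0("Coefficient refers to undeclared level(s): ",
                 paste(coefficients$feature[miss], coefficients$level[miss],
                       sep = "=", collapse = ", ")))
  }
  refs <- features[features$reference, ]
  on_ref <- key(coefficients) %in% key(refs)
  if (any(on_ref)) {
    abort("Reference levels must not carry coefficients.")
  }
  structure(
    list(features = tibble::as_tibble(features),
         coefficients = tibble::as_tibble(coefficients),
         intercept = intercept,
         target_event_rate = target_event_rate),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  features:     ", length(unique(x$features$feature)), "\n")
  cat("  causal terms: ", nrow(x$coefficients), "\n")
  cat("  intercept:    ",
      if (is.null(x$intercept)) "unset" else format(x$intercept), "\n")
  cat("  target rate:  ", format(x$target_event_rate), "\n")
  invisible(x)
}

# expected event rate at intercept b, by exact enumeration of the causal
# feature level combinations weighted by their (independent) marginals
expected_event_rate <- function(config, b) {
  causal <- unique(config$coefficients$feature)
  if (length(causal) == 0) {
    return(plogis(b))
  }
  cells <- lapply(causal, function(f) {
    rows <- config$features[config$features$feature == f, ]
    co <- config$coefficients[config$coefficients$feature == f, ]
    tibble::tibble(
      prob = rows$prob,
      coef = co$coefficient[match(rows$level, co$level)]
    ) |> dplyr::mutate(coef = dplyr::coalesce(.data$coef, 0))
  })
  w <- Reduce(function(u, v) outer(u, v$prob), cells[-1], cells[[1]]$prob)
  lp <- Reduce(function(u, v) outer(u, v$coef, `+`), cells[-1], cells[[1]]$coef)
  sum(as.vector(w) * plogis(b + as.vector(lp)))
}

#' Solve the generator intercept for a target event rate
#'
#' Finds the log-odds intercept `b` such that the expected event rate of the
#' configured outcome model equals `target_rate`.  The expectation is
#' computed by exact enumeration of all level combinations of the causal
#' predictors, weighted by their marginal probabilities (1024 cells for the
#' default seven-predictor model).  Because the expected rate is strictly
#' increasing in `b`, the root is unique; it is located by bracketed
#' root-finding.
#'
#' @param config A [cohort_config()].
#' @param target_rate Event proportion to match; defaults to the
#'   configuration's `target_event_rate`.
#' @param tol Absolute tolerance on the achieved event rate (default 1e-4).
#' @return The intercept (a length-1 double).
#' @export
#' @examples
#' solve_intercept(cohort_config())
solve_intercept <- function(config, target_rate = config$target_event_rate,
                            tol = 1e-4) {
  stopifnot(inherits(config, "cohort_config"))
  if (target_rate <= 0 || target_rate >= 1) {
    abort("`target_rate` must lie strictly between 0 and 1.")
  }
  f <- function(b) expected_event_rate(config, b) - target_rate
  root <- uniroot(f, lower = -40, upper = 40, tol = 1e-12, extendInt = "upX",
                  maxiter = 1000)
  if (abs(f(root$root)) > tol) {
    abort("Intercept search did not converge to the requested tolerance.")
  }
  root$root
}

#' Default DLBCL-emulating generator configuration
#'
#' [cohort_config()] with the intercept solved so the expected event rate is
#' 181/510.
#'
#' @param tol Tolerance passed to [solve_intercept()].
#' @return A `cohort_config` with a set intercept.
#' @export
dlbcl_cohort_config <- function(tol = 1e-4) {
  cfg <- cohort_config()
  cfg$intercept <- solve_intercept(cfg, tol = tol)
  cfg
}

#' Sample a synthetic labelled cohort
#'
#' Draws `n` patients: each feature independently from its configured
#' marginal distribution, then a binary outcome from the logistic model
#' `true_risk = plogis(intercept + sum of the coefficients of the sampled
#' levels)`.  Feature columns are factors whose level order follows the
#' configuration; the outcome column `relapse` is integer 0/1 and the
#' generating probability is kept in `true_risk`.
#'
#' @param config A [cohort_config()] with a set intercept.
#' @param n Number of patients (nonnegative).
#' @param seed Optional integer seed; sampling is reproducible given the
#'   seed and leaves the caller's RNG state untouched.
#' @return A tibble with one factor column per feature plus `relapse`
#'   (integer) and `true_risk` (double).
#' @export
#' @examples
#' cohort <- sample_cohort(dlbcl_cohort_config(), n = 100, seed = 1)
#' mean(cohort$relapse)
sample_cohort <- function(config, n, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0 || n != floor(n)) {
    abort("`n` must be a single nonnegative integer.")
  }
  if (is.null(config$intercept)) {
    abort("Configuration has no intercept; call solve_intercept() first.")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  feats <- split(config$features, factor(config$features$feature,
                                         levels = unique(config$features$feature)))
  cols <- purrr::map(feats, function(rows) {
    lev <- rows$level
    if (n == 0) {
      factor(character(0), levels = lev)
    } else {
      factor(sample(lev, n, replace = TRUE, prob = rows$prob), levels = lev)
    }
  })
  cohort <- tibble::as_tibble(cols)
  lp <- rep(config$intercept, n)
  for (i in seq_len(nrow(config$coefficients))) {
    co <- config$coefficients[i, ]
    lp <- lp + co$coefficient * (cohort[[co$feature]] == co$level)
  }
  cohort$true_risk <- plogis(lp)
  cohort$relapse <- if (n == 0) integer(0) else rbinom(n, 1L, cohort$true_risk)
  cohort
}
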