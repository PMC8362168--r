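#' Feature vocabulary and marginal frequencies of the reference DLBCL cohort
#'
#' Fifteen categorical baseline features recorded for a cohort of 510 diffuse
#' large B-cell lymphoma (DLBCL) patients, with the number of patients in each
#' category.  These marginals drive the synthetic cohort generator: each
#' feature is sampled independently from its empirical distribution
#' (`count / 510`).  The `reference` column marks the category used as the
#' reference level when features are dummy-coded for logistic regression.
#'
#' Seven of the features (sex, stage, IPI, KPS, GCB, CD10, rituximab) carry
#' log-odds coefficients in the outcome model returned by
#' [dlbcl_coefficients()]; the remaining eight (age, WBC, LDH, beta2-MG, ESR,
#' Bcl-6, MUM-1, Ki-67) are generated but do not influence the outcome, so
#' that feature-selection procedures have genuine noise variables to reject.
#'
#' @return A tibble with columns `feature`, `level`, `count`, `prob` and
#'   `reference` (logical), one row per category. Within each feature the
#'   `prob` values sum to 1.
#' @seealso [dlbcl_coefficients()], [cohort_config()], [sample_cohort()]
#' @export
#' @examples
#' dlbcl_features()
dlbcl_features <- function() {
  spec <- list(
    age       = c("<=60" = 288, ">60" = 222),
    sex       = c("Male" = 262, "Female" = 248),
    stage     = c("I" = 50, "II" = 179, "III" = 87, "IV" = 194),
    ipi       = c("Low" = 255, "Low-intermediate" = 102,
                  "High-intermediate" = 101, "High" = 52),
    kps       = c(">=80" = 419, "<80" = 91),
    wbc       = c("Low" = 100, "Normal" = 377, "High" = 33),
    ldh       = c("Normal" = 389, "High" = 121),
    b2mg      = c("Normal" = 373, "High" = 137),
    esr       = c("Normal" = 321, "High" = 189),
    gcb       = c("Yes" = 302, "No" = 208),
    cd10      = c("Negative" = 339, "Positive" = 171),
    bcl6      = c("Negative" = 87, "Positive" = 423),
    mum1      = c("Negative" = 276, "Positive" = 234),
    ki67      = c("<50" = 53, "50~80" = 165, ">80" = 292),
    rituximab = c("Not use" = 290, "Use" = 220)
  )
  # reference level is the first listed category except GCB, whose reference
  # in the outcome model is "No"
  refs <- vapply(spec, function(x) names(x)[1], character(1))
  refs[["gcb"]] <- "No"
  purrr::imap(spec, function(x, nm) {
    tibble::tibble(
      feature = nm, level = names(x), count = unname(x),
      prob = unname(x) / sum(x), reference = names(x) == refs[[nm]]
    )
  }) |>
    purrr::list_rbind()
}

#' Log-odds coefficients of the reference DLBCL outcome model
#'
#' Multivariable logistic-regression coefficients for 3-year relapse in the
#' reference DLBCL cohort (variable selection at p < 0.1).  One row per
#' non-reference dummy of the seven selected predictors; reference levels
#' carry no coefficient.  `odds_ratio` is `exp(coefficient)` as reported to
#' three decimals.  These coefficients define the true outcome model of the
#' synthetic cohort generator; the intercept is not part of the published
#' model and is solved numerically from the marginal event rate (181/510) by
#' [solve_intercept()].
#'
#' @return A tibble with columns `feature`, `level`, `coefficient`,
#'   `odds_ratio` and `p_value`.
#' @seealso [dlbcl_features()], [cohort_config()], [solve_intercept()]
#' @export
#' @examples
#' dlbcl_coefficients()
dlbcl_coefficients <- function() {
  tibble::tribble(
    ~feature,    ~level,              ~coefficient, ~odds_ratio, ~p_value,
    "sex",       "Female",            -0.466,       0.628,       0.037,
    "stage",     "II",                 0.744,       2.105,       0.161,
    "stage",     "III",                1.573,       4.823,       0.006,
    "stage",     "IV",                 1.429,       4.175,       0.011,
    "ipi",       "Low-intermediate",   0.907,       2.478,       0.008,
    "ipi",       "High-intermediate",  0.953,       2.594,       0.013,
    "ipi",       "High",               1.210,       3.352,       0.016,
    "kps",       "<80",                0.734,       2.084,       0.014,
    "gcb",       "Yes",               -0.792,       0.453,       0.041,
    "cd10",      "Positive",          -1.144,       0.318,       0.001,
    "rituximab", "Use",               -0.502,       0.605,       0.027
  )
}

#' Names of the predictors in the reference outcome model
#'
#' The seven features carrying coefficients in [dlbcl_coefficients()]; the
#' default predictor set for [tune_and_fit()] and the experiment driver.
#'
#' @return A character vector of feature names.
#' @export
dlbcl_predictors <- function() {
  unique(dlbcl_coefficients()$feature)
}
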