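#' Score-level calibration testbed with a known true map
#'
#' Generates (score, label) pairs whose true calibration map is known in
#' closed form, for testing calibrators and metrics without any model
#' fitting.  True probabilities are drawn uniformly on (0.01, 0.99), labels
#' are Bernoulli draws, and the observed score is a monotone distortion of
#' the truth,
#' \deqn{s = p^\gamma / (p^\gamma + (1-p)^\gamma),}
#' i.e. a logistic temperature change.  `gamma = 1` leaves scores perfectly
#' calibrated; `gamma > 1` pushes scores towards 0/1 (overconfident, as a
#' naive Bayes classifier does); `gamma < 1` pulls them towards 0.5
#' (underconfident, like normalised SVM scores).  The inverse distortion —
#' the true calibration map — is [true_calibration_map()].
#'
#' @param n Number of examples (nonnegative).
#' @param gamma Distortion exponent, strictly positive.
#' @param seed Optional integer seed.
#' @return A tibble with columns `score`, `label` and `true_prob`.
#' @export
#' @examples
#' tb <- make_score_testbed(1000, gamma = 3, seed = 1)
#' # raw scores are miscalibrated; the true map repairs them
#' head(true_calibration_map(tb$score, gamma = 3) - tb$true_prob)
make_score_testbed <- function(n, gamma = 1, seed = NULL) {
  if (!is.numeric(gamma) || length(gamma) != 1 || !is.finite(gamma) ||
      gamma <= 0) {
    abort("`gamma` must be a single positive number.")
  }
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0 || n != floor(n)) {
    abort("`n` must be a single nonnegative integer.")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  p <- runif(n, 0.01, 0.99)
  tibble::tibble(
    score = distort_probability(p, gamma),
    label = if (n == 0) integer(0) else rbinom(n, 1L, p),
    true_prob = p
  )
}

#' Monotone probability distortion and its inverse
#'
#' `distort_probability()` applies the temperature-style distortion
#' `p^gamma / (p^gamma + (1-p)^gamma)` used by [make_score_testbed()];
#' `true_calibration_map()` is its inverse, i.e. the map that turns a
#' distorted score back into the true event probability.
#'
#' @param p,s Probabilities / scores in `[0, 1]`.
#' @param gamma Distortion exponent, strictly positive.
#' @return Numeric vector in `[0, 1]`.
#' @export
distort_probability <- function(p, gamma) {
  p^gamma / (p^gamma + (1 - p)^gamma)
}

#' @rdname distort_probability
#' @export
true_calibration_map <- function(s, gamma) {
  distort_probability(s, 1 / gamma)
}
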