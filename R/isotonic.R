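#' Isotonic regression calibration via pair-adjacent violators
#'
#' Fits the nonparametric monotone calibration map: the nondecreasing step
#' function minimising the mean squared error to the binary labels over the
#' score-sorted calibration set,
#' \deqn{\min \frac1N \sum_i (f_i - y_i)^2 \quad s.t.\; f_1 \le \dots \le f_N.}
#' The global optimum is computed by the pair-adjacent-violators (PAV)
#' algorithm: walk the examples in ascending score order (ties keep input
#' order) and repeatedly pool any adjacent blocks whose fitted means
#' violate monotonicity, replacing them with their pooled average, until the
#' sequence is nondecreasing.
#'
#' Prediction is interval lookup: a new score takes the fitted level of the
#' block whose score range contains it; scores below the lowest training
#' score take the first level and scores above the highest take the last
#' (clamping).
#'
#' @inheritParams fit_platt
#' @return An object of class `isotonic_calibrator`: a block table with
#'   columns `score_min`, `score_max`, `level`, `n`; levels are
#'   nondecreasing and lie in `[0, 1]`.
#' @seealso [fit_platt()], [fit_rpr()]
#' @export
#' @examples
#' fit <- fit_isotonic_pav(data.frame(score = c(.1, .2, .3), label = c(0, 1, 0)))
#' tidy(fit)
#' predict(fit, c(0.05, 0.25, 0.9))
fit_isotonic_pav <- function(data, score = score, label = label) {
  s <- dplyr::pull(data, {{ score }})
  y <- dplyr::pull(data, {{ label }})
  check_scores_labels(s, y)
  n <- length(s)
  if (n == 0) abort("Cannot fit isotonic regression on an empty dataset.")
  ord <- order(s)                        # stable for numeric (radix)
  s <- s[ord]
  y <- as.numeric(y[ord])

  # PAV with a block stack: (sum, size, first index)
  sum_ <- numeric(n); cnt <- integer(n); first <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    sum_[top] <- y[i]; cnt[top] <- 1L; first[top] <- i
    # pool while the previous block mean strictly exceeds the current one
    while (top > 1L &&
           sum_[top - 1L] / cnt[top - 1L] > sum_[top] / cnt[top]) {
      sum_[top - 1L] <- sum_[top - 1L] + sum_[top]
      cnt[top - 1L] <- cnt[top - 1L] + cnt[top]
      top <- top - 1L
    }
  }
  idx <- seq_len(top)
  last <- c(first[idx][-1] - 1L, n)
  blocks <- tibble::tibble(
    score_min = s[first[idx]],
    score_max = s[last],
    level = sum_[idx] / cnt[idx],
    n = cnt[idx]
  )
  structure(list(blocks = blocks, n = n), class = "isotonic_calibrator")
}

#' @export
predict.isotonic_calibrator <- function(object, newdata, ...) {
  b <- object$blocks
  i <- findInterval(newdata, b$score_min)
  i[i < 1L] <- 1L
  b$level[i]
}

#' @export
print.isotonic_calibrator <- function(x, ...) {
  cat(sprintf("<isotonic_calibrator>  %d blocks from %d examples\n",
              nrow(x$blocks), x$n))
  print(x$blocks, n = 6)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.isotonic_calibrator <- function(x, ...) {
  x$blocks
}

#' @exportS3Method generics::glance
glance.isotonic_calibrator <- function(x, ...) {
  tibble::tibble(n = x$n, n_blocks = nrow(x$blocks),
                 level_min = min(x$blocks$level),
                 level_max = max(x$blocks$level))
}
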