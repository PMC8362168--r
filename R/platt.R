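#' Platt scaling with smoothed targets
#'
#' Fits the sigmoid calibration map
#' \deqn{P(Y = 1 \mid s) = 1 / (1 + \exp(A s + B))}
#' by maximum likelihood on a calibration set of (score, label) pairs.  To
#' avoid overfitting, the binary labels are replaced by smoothed targets:
#' positives become \eqn{(N_+ + 1)/(N_+ + 2)} and negatives
#' \eqn{1/(N_- + 2)}, where \eqn{N_+} and \eqn{N_-} are the class counts of
#' the calibration set.  The smoothed cross-entropy is minimised by damped
#' Newton iteration with backtracking line search, started at
#' `(A, B) = (-1, 0)`, and declared converged when the gradient sup-norm
#' falls below `tol`.  With the usual orientation (higher score, higher
#' risk) the fitted `A` is negative.
#'
#' @param data Data frame of calibration examples.
#' @param score,label Columns holding the score in `[0, 1]` and the 0/1
#'   outcome.  Both classes must be present.
#' @param tol Gradient sup-norm convergence tolerance (default 1e-8).
#' @param max_iter Newton iteration cap.
#' @return An object of class `platt_calibrator` with elements `A`, `B`,
#'   `loss`, `iterations`, `converged`, `n_pos`, `n_neg`.  Use [predict()]
#'   (or [calibrate_scores()]) to map new scores; outputs are strictly
#'   inside (0, 1).
#' @seealso [fit_isotonic_pav()], [fit_rpr()]
#' @export
#' @examples
#' tb <- make_score_testbed(2000, gamma = 3, seed = 1)
#' fit <- fit_platt(tb)
#' tidy(fit)
#' head(predict(fit, tb$score))
fit_platt <- function(data, score = score, label = label, tol = 1e-8,
                      max_iter = 200L) {
  s <- dplyr::pull(data, {{ score }})
  y <- dplyr::pull(data, {{ label }})
  check_scores_labels(s, y)
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("Platt scaling needs both classes in the calibration set.")
  }
  t_pos <- (n_pos + 1) / (n_pos + 2)
  t_neg <- 1 / (n_neg + 2)
  t <- ifelse(y == 1, t_pos, t_neg)

  # p = 1/(1+exp(z)) with z = A s + B; stable cross-entropy pieces:
  # log p = -log1pexp(z),  log(1-p) = z - log1pexp(z)
  log1pexp <- function(z) ifelse(z > 35, z, log1p(exp(z)))
  loss_at <- function(A, B) {
    z <- A * s + B
    sum(t * log1pexp(z) - (1 - t) * (z - log1pexp(z)))
  }
  A <- -1; B <- 0
  loss <- loss_at(A, B)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    z <- A * s + B
    p <- plogis(-z)
    g <- c(sum((t - p) * s), sum(t - p))      # gradient wrt (A, B)
    if (max(abs(g)) < tol) {
      converged <- TRUE
      break
    }
    w <- p * (1 - p)
    H <- matrix(c(sum(w * s^2), sum(w * s), sum(w * s), sum(w)), 2, 2)
    step <- tryCatch(solve(H + diag(1e-12, 2), g),
                     error = function(e) g / max(abs(g)))
    eta <- 1
    repeat {
      A_new <- A - eta * step[1]
      B_new <- B - eta * step[2]
      l_new <- loss_at(A_new, B_new)
      if (is.finite(l_new) && l_new <= loss + 1e-12) break
      eta <- eta / 2
      if (eta < 1e-12) break
    }
    A <- A_new; B <- B_new; loss <- l_new
  }
  structure(list(A = A, B = B, loss = loss, iterations = iter,
                 converged = converged, n_pos = n_pos, n_neg = n_neg),
            class = "platt_calibrator")
}

#' @export
predict.platt_calibrator <- function(object, newdata, ...) {
  plogis(-(object$A * newdata + object$B))
}

#' @export
print.platt_calibrator <- function(x, ...) {
  cat("<platt_calibrator>  1/(1 + exp(A s + B))\n")
  cat(sprintf("  A = %.6f, B = %.6f  (n+ = %d, n- = %d, %s in %d iters)\n",
              x$A, x$B, x$n_pos, x$n_neg,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.platt_calibrator <- function(x, ...) {
  tibble::tibble(term = c("A", "B"), estimate = c(x$A, x$B))
}

#' @exportS3Method generics::glance
glance.platt_calibrator <- function(x, ...) {
  tibble::tibble(loss = x$loss, iterations = x$iterations,
                 converged = x$converged, n_pos = x$n_pos, n_neg = x$n_neg)
}
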