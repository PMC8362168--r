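#' Shape-restricted polynomial regression (RPR) calibration
#'
#' Fits a degree-`k` polynomial calibration map
#' \deqn{f(s) = a_0 + a_1 s + \dots + a_k s^k}
#' by minimising the mean squared error to the binary labels,
#' \deqn{\min_a \frac1N \sum_n \Big(\sum_l a_l s_n^l - y_n\Big)^2,}
#' subject to three convex constraints: the endpoint bounds
#' \eqn{f(\underline{s}) \ge 0} and \eqn{f(\bar{s}) \le 1} (calibrated
#' probabilities stay in `[0, 1]` on the score domain), monotonicity
#' \eqn{f'(s) \ge 0} on \eqn{[\underline{s}, \bar{s}]}, and an l1 budget
#' \eqn{\sum_{l=0}^k |a_l| \le \lambda} against overfitting.
#'
#' The problem is solved as a convex quadratic program: the l1 constraint is
#' handled by coefficient splitting (`a = u - v`, `u, v >= 0`) and the
#' semi-infinite monotonicity constraint is discretised on `grid_size`
#' equally spaced points.  Because a polynomial can still dip between grid
#' points, the fit is audited on a dense grid (2001 points) and any audit
#' points where the derivative is negative are appended to the constraint
#' set and the QP re-solved (cutting planes), until the audit is clean.
#' The active-set solver satisfies active constraints to machine precision,
#' so fitted maps obey all three restrictions to well below 1e-8.
#'
#' @inheritParams fit_platt
#' @param k Polynomial degree, at least 1.
#' @param lambda l1 budget on the coefficients, at least 1 (smaller budgets
#'   exclude the identity map).
#' @param grid_size Number of points of the initial monotonicity grid
#'   (default 201).
#' @param s_range Domain endpoints `(s_lo, s_hi)`; default `c(0, 1)`, the
#'   range of all base-model scores.
#' @return An object of class `rpr_calibrator` with elements
#'   `coefficients` (length `k + 1`, constant term first), `degree`,
#'   `lambda`, `s_lo`, `s_hi`, `objective` (the attained mean squared
#'   error), `refinements` (cutting-plane rounds used).  [predict()] clamps
#'   scores into the domain, evaluates the polynomial and clips to `[0, 1]`
#'   as a numerical guard.
#' @seealso [select_rpr_hyperparams()], [rpr_constraint_slack()]
#' @export
#' @examples
#' tb <- make_score_testbed(2000, gamma = 3, seed = 1)
#' fit <- fit_rpr(tb, k = 8, lambda = 16)
#' fit$objective
#' rpr_constraint_slack(fit)
fit_rpr <- function(data, k = 8, lambda = 16, grid_size = 201,
                    s_range = c(0, 1), score = score, label = label) {
  s <- dplyr::pull(data, {{ score }})
  y <- as.numeric(dplyr::pull(data, {{ label }}))
  check_scores_labels(s, y)
  if (length(s) == 0) abort("Cannot fit RPR on an empty dataset.")
  if (k < 1 || k != floor(k)) abort("`k` must be an integer >= 1.")
  if (lambda < 1) abort("`lambda` must be >= 1 (smaller budgets exclude the identity map).")
  if (grid_size < 2) abort("`grid_size` must be >= 2.")
  s_lo <- s_range[1]; s_hi <- s_range[2]
  if (!(s_hi > s_lo)) abort("`s_range` must be increasing.")

  m <- k + 1L
  S <- outer(s, 0:k, `^`)
  H_a <- 2 * crossprod(S) / length(y)
  d_a <- 2 * crossprod(S, y) / length(y)
  Dsplit <- cbind(diag(m), -diag(m))
  Hx <- crossprod(Dsplit, H_a %*% Dsplit) + diag(1e-10, 2L * m)
  dx <- as.vector(crossprod(Dsplit, d_a))

  deriv_rows <- function(pts) {
    # rows of f'(pts) in the a-basis: (0, 1, 2 s, ..., k s^{k-1})
    cbind(0, vapply(1:k, function(l) l * pts^(l - 1), numeric(length(pts))))
  }
  solve_once <- function(mono_pts) {
    rows_a <- rbind(deriv_rows(mono_pts),
                    s_lo^(0:k),            # f(s_lo) >= 0
                    -(s_hi^(0:k)))         # -f(s_hi) >= -1
    rows_x <- rbind(rows_a %*% Dsplit,
                    matrix(-1, 1L, 2L * m),  # -sum(u+v) >= -lambda
                    diag(2L * m))            # u, v >= 0
    bvec <- c(rep(0, length(mono_pts) + 1L), -1, -lambda, rep(0, 2L * m))
    sol <- tryCatch(
      quadprog::solve.QP(Hx, dx, t(rows_x), bvec),
      error = function(e) abort(paste0("RPR solve failed: ",
                                       conditionMessage(e)))
    )
    x <- sol$solution
    x[1:m] - x[(m + 1L):(2L * m)]
  }

  mono_pts <- seq(s_lo, s_hi, length.out = grid_size)
  audit_pts <- seq(s_lo, s_hi, length.out = 2001)
  refinements <- 0L
  a <- solve_once(mono_pts)
  repeat {
    viol <- audit_pts[drop(deriv_rows(audit_pts) %*% a) < -1e-10]
    if (length(viol) == 0 || refinements >= 10L) break
    refinements <- refinements + 1L
    mono_pts <- sort(unique(c(mono_pts, viol)))
    a <- solve_once(mono_pts)
  }
  objective <- mean((drop(S %*% a) - y)^2)
  structure(list(coefficients = as.vector(a), degree = as.integer(k),
                 lambda = lambda, s_lo = s_lo, s_hi = s_hi,
                 grid_size = as.integer(grid_size), objective = objective,
                 refinements = refinements, n = length(y)),
            class = "rpr_calibrator")
}

eval_poly <- function(a, x) {
  # Horner evaluation, constant term first
  out <- rep(a[length(a)], length(x))
  for (l in rev(seq_len(length(a) - 1L))) out <- out * x + a[l]
  out
}

#' @export
predict.rpr_calibrator <- function(object, newdata, ...) {
  x <- pmin(pmax(newdata, object$s_lo), object$s_hi)
  pmin(pmax(eval_poly(object$coefficients, x), 0), 1)
}

#' Constraint slack audit of a fitted RPR map
#'
#' Recomputes, on a fresh dense grid, how close a fitted shape-restricted
#' polynomial comes to violating its constraints.  All three slacks are
#' nonnegative for a feasible fit; values below `-1e-8` would indicate a
#' solver failure.
#'
#' @param object A fitted [fit_rpr()] map.
#' @param n_grid Audit grid resolution (default 2001).
#' @return A one-row tibble: `min_derivative` (minimum of `f'` on the
#'   grid), `f_lo` (value at the lower endpoint), `one_minus_f_hi`
#'   (headroom below 1 at the upper endpoint), `l1_slack`
#'   (`lambda - sum(|a|)`).
#' @export
rpr_constraint_slack <- function(object, n_grid = 2001) {
  stopifnot(inherits(object, "rpr_calibrator"))
  a <- object$coefficients
  k <- object$degree
  g <- seq(object$s_lo, object$s_hi, length.out = n_grid)
  dpoly <- a[-1] * seq_len(k)
  tibble::tibble(
    min_derivative = min(eval_poly(dpoly, g)),
    f_lo = eval_poly(a, object$s_lo),
    one_minus_f_hi = 1 - eval_poly(a, object$s_hi),
    l1_slack = object$lambda - sum(abs(a))
  )
}

#' @export
print.rpr_calibrator <- function(x, ...) {
  cat(sprintf("<rpr_calibrator>  degree %d, lambda %g on [%g, %g]\n",
              x$degree, x$lambda, x$s_lo, x$s_hi))
  cat(sprintf("  MSE %.6f, l1 %.4f, %d cutting-plane rounds\n",
              x$objective, sum(abs(x$coefficients)), x$refinements))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rpr_calibrator <- function(x, ...) {
  tibble::tibble(term = paste0("a", seq_along(x$coefficients) - 1L),
                 estimate = x$coefficients)
}

#' @exportS3Method generics::glance
glance.rpr_calibrator <- function(x, ...) {
  tibble::tibble(degree = x$degree, lambda = x$lambda,
                 objective = x$objective, l1 = sum(abs(x$coefficients)),
                 refinements = x$refinements, n = x$n)
}

#' Select RPR hyperparameters by stratified cross-validation
#'
#' Grid search over polynomial degree and l1 budget by stratified `folds`-
#' fold cross-validation on the calibration set, scoring candidates by mean
#' validation squared error (the training objective).  Ties are broken
#' toward the smaller degree, then the smaller budget.  If a fold ends up
#' single-class the folds are redrawn with a new seed, up to 5 attempts.
#'
#' @inheritParams fit_platt
#' @param k_grid Candidate degrees (default 4..20).
#' @param lambda_grid Candidate l1 budgets (default `4^(0:5)`).
#' @param folds Number of CV folds (default 3).
#' @param seed Optional integer seed for the fold draw.
#' @param grid_size,s_range Passed to [fit_rpr()].
#' @return A list with `k`, `lambda` and `cv`, a tibble of mean validation
#'   errors per candidate.
#' @export
select_rpr_hyperparams <- function(data, k_grid = 4:20,
                                   lambda_grid = 4^(0:5), folds = 3,
                                   seed = NULL, grid_size = 201,
                                   s_range = c(0, 1),
                                   score = score, label = label) {
  s <- dplyr::pull(data, {{ score }})
  y <- dplyr::pull(data, {{ label }})
  check_scores_labels(s, y)
  if (length(k_grid) == 0 || length(lambda_grid) == 0) {
    abort("Hyperparameter grids must be non-empty.")
  }
  fold_id <- draw_stratified_folds(y, folds, seed)
  grid <- tidyr::expand_grid(k = sort(k_grid), lambda = sort(lambda_grid))
  err <- matrix(NA_real_, nrow(grid), folds)
  df <- tibble::tibble(score = s, label = y)
  for (f in seq_len(folds)) {
    tr <- df[fold_id != f, ]
    va <- df[fold_id == f, ]
    for (i in seq_len(nrow(grid))) {
      fit <- fit_rpr(tr, k = grid$k[i], lambda = grid$lambda[i],
                     grid_size = grid_size, s_range = s_range)
      err[i, f] <- mean((predict(fit, va$score) - va$label)^2)
    }
  }
  grid$cv_error <- rowMeans(err)
  best <- which.min(grid$cv_error)       # grid ordered k asc, lambda asc
  list(k = grid$k[best], lambda = grid$lambda[best], cv = grid)
}

# stratified fold assignment: within each class, shuffle and deal round-robin;
# redraws (new seed) if any fold misses a class, then errors after 5 tries
draw_stratified_folds <- function(y, folds, seed = NULL) {
  if (folds < 2) abort("`folds` must be at least 2.")
  draw <- function(seed_i) {
    if (!is.null(seed_i)) withr::local_seed(seed_i)
    id <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      id[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(folds), length(idx))
    }
    id
  }
  for (attempt in 0:4) {
    id <- draw(if (is.null(seed)) NULL else seed + attempt)
    ok <- all(vapply(seq_len(folds), function(f) {
      length(unique(y[id == f])) == 2L && sum(id != f & y == 1) > 0 &&
        sum(id != f & y == 0) > 0
    }, logical(1)))
    if (ok) return(id)
  }
  abort("Could not draw stratified folds with both classes in every fold.")
}
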