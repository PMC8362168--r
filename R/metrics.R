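# Discrimination and calibration metrics.
#
# User-facing functions take a data frame with a score column and a binary
# label column (defaults `score`, `label`) and return scalars or tibbles;
# the internal dot-prefixed versions work on bare vectors and are what the
# experiment driver calls in its inner loop.

check_scores_labels <- function(scores, labels, call = rlang::caller_env()) {
  if (length(scores) != length(labels)) {
    abort("`score` and `label` must have the same length.", call = call)
  }
  if (anyNA(scores) || anyNA(labels)) {
    abort("Scores and labels must not contain missing values.", call = call)
  }
  if (!all(labels %in% c(0, 1))) {
    abort("Labels must be 0 or 1.", call = call)
  }
}

.auc <- function(scores, labels) {
  check_scores_labels(scores, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort("AUC is undefined when only one class is present.")
  }
  r <- rank(scores)                      # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with tied scores counted 1/2.  Invariant
#' under any strictly increasing transform of the scores.
#'
#' @param data Data frame of predictions.
#' @param score,label Columns holding the predicted score and the 0/1
#'   outcome.
#' @return A length-1 double in `[0, 1]`.
#' @export
#' @examples
#' auc(data.frame(score = c(.1, .4, .35, .8), label = c(0, 0, 1, 1)))
auc <- function(data, score = score, label = label) {
  .auc(dplyr::pull(data, {{ score }}), dplyr::pull(data, {{ label }}))
}

.brier <- function(scores, labels) {
  check_scores_labels(scores, labels)
  if (length(scores) == 0) abort("Brier score of an empty dataset is undefined.")
  mean((scores - labels)^2)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and binary outcome.
#'
#' @inheritParams auc
#' @return A length-1 double in `[0, 1]`.
#' @export
brier <- function(data, score = score, label = label) {
  .brier(dplyr::pull(data, {{ score }}), dplyr::pull(data, {{ label }}))
}

.bin_equal_size <- function(scores, labels, k = 10) {
  check_scores_labels(scores, labels)
  n <- length(scores)
  if (k < 1 || k != floor(k)) abort("`k` must be a positive integer.")
  if (n < k) abort("Need at least `k` observations to form `k` bins.")
  ord <- order(scores)                   # radix sort: ties keep input order
  s <- scores[ord]
  y <- labels[ord]
  base <- n %/% k
  sizes <- rep(base, k)
  rem <- n %% k
  if (rem > 0) sizes[seq_len(rem)] <- base + 1
  idx <- rep(seq_len(k), sizes)
  out <- tibble::tibble(
    bin = seq_len(k),
    n = as.integer(sizes),
    p_mean = as.vector(tapply(s, idx, mean)),
    o_rate = as.vector(tapply(y, idx, mean)),
    exp_pos = as.vector(tapply(s, idx, sum)),
    obs_pos = as.vector(tapply(y, idx, sum))
  )
  out$exp_neg <- out$n - out$exp_pos
  out$obs_neg <- out$n - out$obs_pos
  class(out) <- c("calibration_bins", class(out))
  out
}

#' Equal-size calibration bins
#'
#' Sorts examples by predicted score (stable: ties keep input order) and
#' splits them into `k` bins whose sizes differ by at most one, the larger
#' bins coming first.  The per-bin mean prediction, observed event rate and
#' observed/expected class totals are the backbone of the Hosmer-Lemeshow
#' test, [ece()] and [mce()], and of reliability diagrams.
#'
#' @inheritParams auc
#' @param k Number of bins (default 10, the decile convention).
#' @return A tibble of class `calibration_bins` with columns `bin`, `n`,
#'   `p_mean`, `o_rate`, `exp_pos`, `obs_pos`, `exp_neg`, `obs_neg`.
#' @export
#' @examples
#' bin_equal_size(make_score_testbed(200, gamma = 2, seed = 1), k = 5)
bin_equal_size <- function(data, k = 10, score = score, label = label) {
  .bin_equal_size(dplyr::pull(data, {{ score }}),
                  dplyr::pull(data, {{ label }}), k = k)
}

# merge bins whose expected counts underflow, folding outer bins toward the
# centre; near-deterministic predictions (naive Bayes) otherwise divide by 0
merge_degenerate_bins <- function(bins, eps = 1e-10) {
  b <- as.data.frame(bins)[c("n", "exp_pos", "obs_pos", "exp_neg", "obs_neg")]
  repeat {
    bad <- which(b$exp_pos < eps | b$exp_neg < eps)
    if (length(bad) == 0 || nrow(b) == 1) break
    i <- bad[1]
    j <- if (i <= nrow(b) / 2) i + 1 else i - 1
    lo <- min(i, j); hi <- max(i, j)
    b[lo, ] <- b[lo, ] + b[hi, ]
    b <- b[-hi, , drop = FALSE]
  }
  b
}

#' Hosmer-Lemeshow statistic of a bin table
#'
#' \eqn{C = \sum_i \sum_{c \in \{0,1\}} (O_i^c - P_i^c)^2 / P_i^c}, the
#' chi-square-type distance between observed and expected class counts per
#' bin.  Bins whose expected count in either class underflows (below 1e-10)
#' are merged with their neighbour toward the centre before summing.
#'
#' @param bins A [bin_equal_size()] table.
#' @return A length-1 double, together with attribute `k_effective`, the
#'   number of bins after degenerate-bin merging.
#' @export
hl_statistic <- function(bins) {
  b <- merge_degenerate_bins(bins)
  if (any(b$exp_pos <= 0 | b$exp_neg <= 0)) {
    abort("Zero expected count remains after bin merging.")
  }
  stat <- sum((b$obs_pos - b$exp_pos)^2 / b$exp_pos +
              (b$obs_neg - b$exp_neg)^2 / b$exp_neg)
  attr(stat, "k_effective") <- nrow(b)
  stat
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Compares the [hl_statistic()] of a bin table against a chi-square
#' reference with `k - 2` degrees of freedom, where `k` is the number of
#' bins after degenerate-bin merging.  Large statistics (small p-values)
#' indicate miscalibration; in this package's experiment driver a model is
#' counted as well-calibrated in a repetition when p > 0.05.
#'
#' @param bins A [bin_equal_size()] table with at least 3 effective bins.
#' @return A one-row tibble with `statistic`, `df` and `p_value`.
#' @export
#' @examples
#' tb <- make_score_testbed(500, gamma = 1, seed = 1)
#' hosmer_lemeshow(bin_equal_size(tb))
hosmer_lemeshow <- function(bins) {
  stat <- hl_statistic(bins)
  df <- attr(stat, "k_effective") - 2L
  if (df < 1) {
    abort(paste0("Hosmer-Lemeshow test needs at least 3 bins (df = ",
                 df, ")."))
  }
  tibble::tibble(statistic = as.numeric(stat), df = df,
                 p_value = pchisq(as.numeric(stat), df, lower.tail = FALSE))
}

#' Expected and maximum calibration error
#'
#' `ece()` is the mean, and `mce()` the maximum, of the absolute gap between
#' mean predicted risk and observed event rate across the bins, reported in
#' percentage points (the `[0, 1]`-scale gap times 100).
#'
#' @param bins A [bin_equal_size()] table.
#' @return A length-1 double in percentage points.
#' @export
#' @examples
#' tb <- make_score_testbed(2000, gamma = 3, seed = 1)
#' ece(bin_equal_size(tb))
ece <- function(bins) {
  100 * mean(abs(bins$p_mean - bins$o_rate))
}

#' @rdname ece
#' @export
mce <- function(bins) {
  100 * max(abs(bins$p_mean - bins$o_rate))
}

.evaluate_scores <- function(scores, labels, k = 10) {
  bins <- .bin_equal_size(scores, labels, k = k)
  hl <- tryCatch(hosmer_lemeshow(bins),
                 error = function(e) tibble::tibble(statistic = NA_real_,
                                                    df = NA_integer_,
                                                    p_value = NA_real_))
  tibble::tibble(
    auc = .auc(scores, labels),
    ece = ece(bins),
    mce = mce(bins),
    brier = .brier(scores, labels),
    hl_statistic = hl$statistic,
    hl_df = hl$df,
    hl_p = hl$p_value
  )
}

#' Evaluate a score vector on all study metrics
#'
#' One-stop evaluation: AUC, ECE, MCE, Brier score and the Hosmer-Lemeshow
#' test on `k` equal-size bins.  If the H-L test is undefined (fewer than 3
#' effective bins after merging) its columns are `NA`.
#'
#' @inheritParams auc
#' @param k Number of calibration bins.
#' @return A one-row tibble with columns `auc`, `ece`, `mce`, `brier`,
#'   `hl_statistic`, `hl_df`, `hl_p`.
#' @export
#' @examples
#' evaluate_scores(make_score_testbed(500, gamma = 2, seed = 1))
evaluate_scores <- function(data, k = 10, score = score, label = label) {
  .evaluate_scores(dplyr::pull(data, {{ score }}),
                   dplyr::pull(data, {{ label }}), k = k)
}
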