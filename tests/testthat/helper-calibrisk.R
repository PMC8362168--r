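# Shared fixtures and independent oracles, built in code at test time.

# default generator configuration with the intercept solved, computed once
default_config <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- dlbcl_cohort_config()
    cache
  }
})

# a mid-sized cohort reused across model tests
fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- sample_cohort(default_config(), 510, seed = 42)
    cache
  }
})

# independent oracle for isotonic least squares: the minimax formula
# f_i = max_{j <= i} min_{k >= i} mean(y[j..k])
iso_minimax <- function(y) {
  n <- length(y)
  cs <- cumsum(c(0, y))
  seg_mean <- function(j, k) (cs[k + 1] - cs[j]) / (k - j + 1)
  vapply(seq_len(n), function(i) {
    max(vapply(seq_len(i), function(j) {
      min(vapply(i:n, function(k) seg_mean(j, k), numeric(1)))
    }, numeric(1)))
  }, numeric(1))
}

# reduced hyperparameter grids for scaled-down experiment runs (subsets of
# the full protocol grids; FFNN width reduced for the single-CPU budget)
scaled_specs <- function() {
  list(
    rf = model_spec("rf", ntree = c(500, 1000)),
    svm = model_spec("svm", cost = c(0.1, 1, 10), gamma = c(0.01, 0.1, 1)),
    ffnn = model_spec("ffnn", hidden = 50, epochs = c(10, 25, 50))
  )
}

scaled_experiment_config <- function(n_repetitions,
                                     families = c("nb", "lr", "rf", "svm",
                                                  "ffnn")) {
  experiment_config(
    n_repetitions = n_repetitions,
    families = families,
    specs = scaled_specs(),
    rpr_k_grid = c(4, 6, 8),
    rpr_lambda_grid = c(1, 4, 16)
  )
}
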