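# Five base risk models behind one surface: naive Bayes, logistic
# regression, random forest, SVM and a single-hidden-layer feedforward
# network, each exposed as a probability scorer on [0, 1].

#' Specify a base risk model and its hyperparameter grid
#'
#' Families and default grids:
#' * `"nb"` — categorical naive Bayes with Laplace smoothing `laplace = 1`;
#'   no tuning.
#' * `"lr"` — multivariable logistic regression (reference-coded dummies);
#'   no tuning.
#' * `"rf"` — random forest; grid over `ntree` in `{500, 600, ..., 1500}`
#'   and `mtry` (candidate attributes per split) in `{2, 3}`.
#' * `"svm"` — support vector machine with linear or Gaussian kernel,
#'   `cost` and (Gaussian only) `gamma` in `{10^-4, ..., 10^4}`; the real-
#'   valued decision score is min-max normalised to `[0, 1]` with
#'   training-set bounds.
#' * `"ffnn"` — feedforward network with one hidden layer of `hidden`
#'   logistic units (default 1000) and a sigmoid output trained on
#'   cross-entropy; the effective number of training epochs (`epochs`
#'   grid for the optimiser iteration cap) is chosen on validation folds
#'   by log-loss, emulating early stopping.
#'
#' Grids may be narrowed (subsets of the defaults) for scaled-down runs.
#'
#' @param family One of `"nb"`, `"lr"`, `"rf"`, `"svm"`, `"ffnn"`
#'   (case-insensitive).
#' @param ntree,mtry Random-forest grid.
#' @param kernel,cost,gamma SVM grid (`gamma` applies to the Gaussian
#'   kernel only).
#' @param hidden,epochs,decay FFNN architecture and training grid.
#' @param laplace Naive Bayes smoothing count.
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec("rf", ntree = c(500, 1000))
model_spec <- function(family = c("nb", "lr", "rf", "svm", "ffnn"),
                       ntree = seq(500, 1500, by = 100), mtry = c(2, 3),
                       kernel = c("linear", "radial"),
                       cost = 10^(-4:4), gamma = 10^(-4:4),
                       hidden = 1000, epochs = c(10, 25, 50, 100, 200),
                       decay = 0,
                       laplace = 1) {
  family <- tolower(family)
  family <- match.arg(family)
  if (family == "rf") {
    if (length(ntree) == 0 || length(mtry) == 0) abort("RF grid must be non-empty.")
    if (!all(ntree %in% seq(500, 1500, by = 100))) {
      abort("`ntree` values must come from {500, 600, ..., 1500}.")
    }
    if (!all(mtry %in% c(2, 3))) abort("`mtry` values must come from {2, 3}.")
  }
  if (family == "svm") {
    kernel <- match.arg(kernel, c("linear", "radial"), several.ok = TRUE)
    if (length(cost) == 0) abort("SVM grid must be non-empty.")
    if (!all(cost %in% 10^(-4:4)) || !all(gamma %in% 10^(-4:4))) {
      abort("SVM `cost` and `gamma` values must come from {10^-4, ..., 10^4}.")
    }
  }
  if (family == "ffnn") {
    if (length(epochs) == 0) abort("FFNN epoch grid must be non-empty.")
    if (hidden < 1) abort("`hidden` must be positive.")
  }
  structure(list(family = family,
                 grid = list(ntree = ntree, mtry = mtry, kernel = kernel,
                             cost = cost, gamma = gamma, hidden = hidden,
                             epochs = epochs, decay = decay,
                             laplace = laplace)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", toupper(x$family), "\n")
  invisible(x)
}

# ---- feature encoding -----------------------------------------------------

# record the category vocabulary of each feature; reference level first for
# features with a known reference (used by reference-coded LR dummies)
build_encoder <- function(data, features) {
  vocab <- dlbcl_features()
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing feature column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  levels_map <- lapply(setNames(features, features), function(f) {
    known <- vocab[vocab$feature == f, ]
    if (nrow(known) > 0) {
      list(levels = known$level, ref = known$level[known$reference][1])
    } else {
      lev <- levels(factor(data[[f]]))
      list(levels = lev, ref = lev[1])
    }
  })
  levels_map
}

# factors in vocabulary order; error on categories outside the vocabulary
encode_factors <- function(data, encoder, ref_first = FALSE) {
  cols <- lapply(names(encoder), function(f) {
    lev <- encoder[[f]]$levels
    if (ref_first) {
      lev <- c(encoder[[f]]$ref, setdiff(lev, encoder[[f]]$ref))
    }
    x <- as.character(data[[f]])
    bad <- !x %in% lev & !is.na(x)
    if (any(bad)) {
      abort(paste0("Unknown category \"", x[which(bad)[1]],
                   "\" in feature `", f, "` (row ", which(bad)[1], ")."))
    }
    factor(x, levels = lev)
  })
  out <- as.data.frame(setNames(cols, names(encoder)),
                       stringsAsFactors = TRUE)
  out
}

# full one-hot (all levels) numeric matrix for SVM / FFNN
encode_onehot <- function(data, encoder) {
  fct <- encode_factors(data, encoder)
  cols <- lapply(names(encoder), function(f) {
    lev <- encoder[[f]]$levels
    m <- vapply(lev, function(l) as.numeric(fct[[f]] == l),
                numeric(nrow(fct)))
    if (nrow(fct) == 0) m <- matrix(numeric(0), 0, length(lev))
    colnames(m) <- paste(f, lev, sep = ".")
    m
  })
  do.call(cbind, cols)
}

# ---- per-family fit / predict ---------------------------------------------

fit_family <- function(family, data, y, encoder, params, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  yf <- factor(y, levels = c(0, 1))
  switch(family,
    nb = {
      x <- encode_factors(data, encoder)
      list(fit = e1071::naiveBayes(x, yf, laplace = params$laplace))
    },
    lr = {
      x <- encode_factors(data, encoder, ref_first = TRUE)
      x$.y <- y
      list(fit = glm(.y ~ ., data = x, family = binomial()))
    },
    rf = {
      x <- encode_factors(data, encoder)
      list(fit = randomForest::randomForest(
        x, yf, ntree = params$ntree, mtry = min(params$mtry, ncol(x))))
    },
    svm = {
      x <- encode_onehot(data, encoder)
      fit <- if (params$kernel == "linear") {
        e1071::svm(x, yf, kernel = "linear", cost = params$cost,
                   scale = FALSE)
      } else {
        e1071::svm(x, yf, kernel = "radial", cost = params$cost,
                   gamma = params$gamma, scale = FALSE)
      }
      dv <- decision_values(fit, x)
      list(fit = fit, svm_lo = min(dv), svm_hi = max(dv))
    },
    ffnn = {
      x <- encode_onehot(data, encoder)
      size <- params$hidden
      nw <- (ncol(x) + 1) * size + size + 1
      fit <- nnet::nnet(x, as.numeric(y), size = size, decay = params$decay,
                        maxit = params$epochs, entropy = TRUE,
                        MaxNWts = nw + 10, trace = FALSE)
      list(fit = fit)
    },
    abort(paste0("Unknown model family: ", family))
  )
}

# SVM decision values oriented so that larger means higher relapse risk
decision_values <- function(fit, x) {
  dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
  lab <- colnames(dv)[1]                 # "a/b": positive favours class a
  first <- strsplit(lab, "/", fixed = TRUE)[[1]][1]
  if (first == "1") drop(dv) else -drop(dv)
}

# min-max normalisation of decision values with training-set bounds; values
# outside the bounds clip to [0, 1], degenerate bounds map everything to 0.5
minmax_scale <- function(dv, lo, hi) {
  if (hi == lo) return(rep(0.5, length(dv)))
  pmin(pmax((dv - lo) / (hi - lo), 0), 1)
}

predict_family <- function(family, obj, data, encoder) {
  switch(family,
    nb = {
      x <- encode_factors(data, encoder)
      unname(predict(obj$fit, x, type = "raw")[, "1"])
    },
    lr = {
      x <- encode_factors(data, encoder, ref_first = TRUE)
      unname(predict(obj$fit, newdata = x, type = "response"))
    },
    rf = {
      x <- encode_factors(data, encoder)
      unname(predict(obj$fit, x, type = "prob")[, "1"])
    },
    svm = {
      x <- encode_onehot(data, encoder)
      minmax_scale(decision_values(obj$fit, x), obj$svm_lo, obj$svm_hi)
    },
    ffnn = {
      x <- encode_onehot(data, encoder)
      pmin(pmax(drop(predict(obj$fit, x)), 0), 1)
    }
  )
}

# hyperparameter candidates, ordered so ties resolve to the simplest model
family_grid <- function(spec) {
  g <- spec$grid
  switch(spec$family,
    nb = tibble::tibble(laplace = g$laplace[1]),
    lr = tibble::tibble(.fixed = TRUE),
    rf = tidyr::expand_grid(ntree = sort(g$ntree), mtry = sort(g$mtry)) |>
      dplyr::arrange(.data$ntree, .data$mtry),
    svm = dplyr::bind_rows(
      if ("linear" %in% g$kernel)
        tidyr::expand_grid(kernel = "linear", cost = sort(g$cost),
                           gamma = NA_real_),
      if ("radial" %in% g$kernel)
        tidyr::expand_grid(kernel = "radial", cost = sort(g$cost),
                           gamma = sort(g$gamma))
    ),
    ffnn = tibble::tibble(hidden = g$hidden, epochs = sort(g$epochs),
                          decay = g$decay)
  )
}

#' Tune and fit a base risk model
#'
#' Chooses hyperparameters by stratified `folds`-fold cross-validation on
#' the training cohort, maximising validation AUC (ties broken toward the
#' simplest candidate: fewest trees, linear kernel and smallest cost,
#' fewest epochs), then refits the winning configuration on the full
#' training data.  Naive Bayes and logistic regression have nothing to
#' tune but still run through the folds, because the out-of-fold
#' (validation-set) predictions of the selected configuration are retained
#' as the leakage-free training set for the probability calibrators.
#'
#' @param spec A [model_spec()].
#' @param data Training cohort: one row per patient, categorical feature
#'   columns plus a 0/1 outcome column.
#' @param features Feature columns to use as predictors (default the seven
#'   predictors of the reference outcome model).
#' @param label Name of the outcome column.
#' @param folds Number of CV folds (default 3).
#' @param seed Optional integer seed controlling fold draws and the
#'   stochastic learners.
#' @return An object of class `risk_model` carrying the fitted learner, the
#'   chosen hyperparameters (`$hyper`), the CV table (`$cv`) and the
#'   out-of-fold calibration scores (`$oof`, a tibble of `score`, `label`).
#' @seealso [predict_risk()]
#' @export
#' @examples
#' cohort <- sample_cohort(dlbcl_cohort_config(), n = 300, seed = 1)
#' fit <- tune_and_fit(model_spec("lr"), cohort, seed = 1)
#' summary(fit$oof$score)
tune_and_fit <- function(spec, data, features = dlbcl_predictors(),
                         label = "relapse", folds = 3, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (nrow(data) == 0) abort("Training data is empty.")
  y <- data[[label]]
  if (is.null(y)) abort(paste0("No outcome column `", label, "`."))
  if (length(unique(y)) < 2) {
    abort("Training data must contain both classes.")
  }
  encoder <- build_encoder(data, features)
  grid <- family_grid(spec)
  fold_id <- draw_stratified_folds(y, folds,
                                   if (is.null(seed)) NULL else seed)
  n <- nrow(data)
  val_scores <- matrix(NA_real_, n, nrow(grid))
  fold_score <- matrix(NA_real_, nrow(grid), folds)
  for (f in seq_len(folds)) {
    tr_idx <- fold_id != f
    tr <- data[tr_idx, , drop = FALSE]
    va <- data[!tr_idx, , drop = FALSE]
    for (i in seq_len(nrow(grid))) {
      params <- as.list(grid[i, ])
      params$hidden <- spec$grid$hidden
      params$decay <- spec$grid$decay
      params$laplace <- spec$grid$laplace
      obj <- fit_family(spec$family, tr, y[tr_idx], encoder, params,
                        seed = if (is.null(seed)) NULL
                               else seed + 1000L * i + f)
      sc <- predict_family(spec$family, obj, va, encoder)
      val_scores[!tr_idx, i] <- sc
      fold_score[i, f] <- if (spec$family == "ffnn") {
        # epoch choice emulates early stopping: maximise the validation
        # log-likelihood (equivalently minimise cross-entropy)
        pv <- pmin(pmax(sc, 1e-10), 1 - 1e-10)
        yv <- y[!tr_idx]
        mean(yv * log(pv) + (1 - yv) * log1p(-pv))
      } else {
        .auc(sc, y[!tr_idx])
      }
    }
  }
  mean_score <- rowMeans(fold_score)
  best <- which.max(mean_score)          # first max: simplest candidate wins
  params <- as.list(grid[best, ])
  params$hidden <- spec$grid$hidden
  params$decay <- spec$grid$decay
  params$laplace <- spec$grid$laplace
  final <- fit_family(spec$family, data, y, encoder, params,
                      seed = if (is.null(seed)) NULL else seed + 1L)
  cv <- grid
  cv$cv_score <- mean_score
  structure(
    c(final,
      list(family = spec$family, features = features, label = label,
           encoder = encoder, hyper = params, cv = cv,
           oof = tibble::tibble(score = val_scores[, best],
                                label = as.numeric(y)))),
    class = "risk_model")
}

#' Predict relapse risk with a fitted base model
#'
#' Maps a cohort through the fitted learner to probabilities in `[0, 1]`:
#' posterior probabilities for NB/LR/FFNN, the fraction of trees voting for
#' relapse for RF, and min-max-normalised decision values (training-set
#' bounds, clipped) for the SVM.  Categories unseen at fit time raise an
#' error naming the offending feature.
#'
#' @param model A [tune_and_fit()] result.
#' @param data Cohort to score.
#' @return A numeric vector of probabilities, one per row.
#' @export
predict_risk <- function(model, data) {
  stopifnot(inherits(model, "risk_model"))
  predict_family(model$family, model, data, model$encoder)
}

#' @export
predict.risk_model <- function(object, newdata, ...) {
  predict_risk(object, newdata)
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model>", toupper(x$family), "\n")
  hy <- x$hyper[!vapply(x$hyper, function(v) is.null(v) || all(is.na(v)),
                        logical(1))]
  if (length(hy)) {
    cat("  hyper:", paste(names(hy), vapply(hy, format, character(1)),
                          sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.risk_model <- function(x, ...) {
  x$cv
}

#' @exportS3Method generics::glance
glance.risk_model <- function(x, ...) {
  tibble::tibble(family = toupper(x$family),
                 n_train = nrow(x$oof),
                 cv_score = max(x$cv$cv_score))
}

# ---- feature-selection analyses -------------------------------------------

#' Logistic-regression variable selection
#'
#' Fits a multivariable logistic regression of the outcome on all supplied
#' features (reference-coded dummies) and keeps the variables whose
#' smallest Wald p-value across their dummies is below `alpha` (default
#' 0.1).  Selection is at the variable level, so a multi-level variable is
#' retained in full as soon as one of its dummies clears the screen.
#'
#' @param data Cohort with categorical feature columns and a 0/1 outcome.
#' @param alpha Variable-level significance screen (default 0.1).
#' @param features Feature columns to screen; default all columns except
#'   the outcome and `true_risk`.
#' @param label Outcome column name.
#' @return A tibble of the selected variables' non-reference dummies with
#'   columns `variable`, `grouping`, `coefficient`, `odds_ratio`
#'   (`exp(coefficient)`) and `p_value`; the unfiltered table is attached
#'   as attribute `"full"`.
#' @export
select_predictors_lr <- function(data, alpha = 0.1, features = NULL,
                                 label = "relapse") {
  if (is.null(features)) {
    features <- setdiff(names(data), c(label, "true_risk"))
  }
  y <- data[[label]]
  if (length(unique(y)) < 2) abort("Outcome must contain both classes.")
  encoder <- build_encoder(data, features)
  x <- encode_factors(data, encoder, ref_first = TRUE)
  x$.y <- y
  fit <- glm(.y ~ ., data = x, family = binomial())
  sm <- summary(fit)$coefficients
  if (!fit$converged || any(sm[, "Std. Error"] > 50)) {
    abort("Logistic regression did not converge (possible separation).")
  }
  rows <- purrr::map(features, function(f) {
    lev <- levels(x[[f]])[-1]            # non-reference levels
    term <- paste0(f, lev)
    keep <- term %in% rownames(sm)
    tibble::tibble(variable = f, grouping = lev[keep],
                   coefficient = sm[term[keep], "Estimate"],
                   odds_ratio = exp(sm[term[keep], "Estimate"]),
                   p_value = sm[term[keep], "Pr(>|z|)"])
  }) |> purrr::list_rbind()
  min_p <- tapply(rows$p_value, rows$variable, min)
  selected <- names(min_p)[min_p < alpha]
  out <- rows[rows$variable %in% selected, ]
  attr(out, "full") <- rows
  out
}

#' Random-forest variable importance ranking
#'
#' Fits a random forest on all supplied features and returns both standard
#' importance measures: mean decrease in accuracy (out-of-bag permutation
#' importance) and mean decrease in Gini impurity, together with the rank
#' order of each (rank 1 = most important).
#'
#' @inheritParams select_predictors_lr
#' @param ntree Number of trees (default 1000).
#' @param seed Optional integer seed.
#' @return A tibble with columns `feature`, `mean_decrease_accuracy`,
#'   `mean_decrease_gini`, `rank_accuracy`, `rank_gini`.
#' @export
rank_importance_rf <- function(data, features = NULL, label = "relapse",
                               ntree = 1000, seed = NULL) {
  if (is.null(features)) {
    features <- setdiff(names(data), c(label, "true_risk"))
  }
  y <- factor(data[[label]], levels = c(0, 1))
  if (length(unique(data[[label]])) < 2) {
    abort("Outcome must contain both classes.")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  encoder <- build_encoder(data, features)
  x <- encode_factors(data, encoder)
  fit <- randomForest::randomForest(x, y, ntree = ntree, importance = TRUE)
  imp <- randomForest::importance(fit)
  tibble::tibble(
    feature = rownames(imp),
    mean_decrease_accuracy = unname(imp[, "MeanDecreaseAccuracy"]),
    mean_decrease_gini = unname(imp[, "MeanDecreaseGini"]),
    rank_accuracy = unname(rank(-imp[, "MeanDecreaseAccuracy"],
                                ties.method = "min")),
    rank_gini = unname(rank(-imp[, "MeanDecreaseGini"],
                            ties.method = "min"))
  )
}
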