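#' Configuration for feature-subset selection
#'
#' @param n_folds External cross-validation folds (default 10).
#' @param k_grid Numbers of top features to evaluate; `NULL` uses an
#'   approximately geometric ladder `1, 2, 5, 10, 25, 50, 100, 250, 500,
#'   1000, ...` capped at the feature count.
#' @param rfe An [rfe_config()] for the per-fold feature ranking.
#' @param C_grid,gamma_grid Log-2 spaced grids for the RBF-SVM penalty
#'   (`2^-5 .. 2^15`) and kernel width (`2^-15 .. 2^3`).
#' @param tune_folds Internal cross-validation folds for tuning (default 10).
#' @param metric `"accuracy"` (the competition metric) or `"balanced"`
#'   (mean of class recalls, for heavily skewed sites).
#' @param seed Integer seed; folds and per-fold rankings derive from it.
#' @return Object of class `select_config`.
#' @export
select_config <- function(n_folds = 10, k_grid = NULL, rfe = rfe_config(),
                          C_grid = 2^seq(-5, 15, by = 2),
                          gamma_grid = 2^seq(-15, 3, by = 2),
                          tune_folds = 10,
                          metric = c("accuracy", "balanced"),
                          seed = 1) {
  metric <- match.arg(metric)
  structure(list(n_folds = as.integer(n_folds), k_grid = k_grid, rfe = rfe,
                 C_grid = C_grid, gamma_grid = gamma_grid,
                 tune_folds = as.integer(tune_folds), metric = metric,
                 seed = as.integer(seed)),
            class = "select_config")
}

default_k_grid <- function(n_features) {
  ladder <- c(1, 2, 5, 10, 25, 50, 100, 250, 500,
              1000 * 10^(0:6) %x% c(1, 2.5, 5))
  ks <- unique(c(ladder[ladder < n_features], n_features))
  as.integer(sort(ks))
}

prediction_score <- function(truth, pred, metric) {
  if (metric == "balanced") {
    mean(vapply(levels(truth), function(cl) {
      idx <- truth == cl
      if (!any(idx)) return(NA_real_)
      mean(pred[idx] == cl)
    }, numeric(1)), na.rm = TRUE)
  } else {
    mean(pred == truth)
  }
}

#' Tune RBF-SVM hyperparameters by internal cross-validation
#'
#' Grid search over the soft-margin penalty `C` and the RBF kernel width
#' `gamma` by stratified internal cross-validation accuracy. Ties resolve to
#' the smaller `C`, then the smaller `gamma`. Features are standardized
#' within each training split.
#'
#' @param X Observations x features matrix.
#' @param y Two-class factor.
#' @param C_grid,gamma_grid Hyperparameter grids (log-2 spaced by default).
#' @param n_folds Internal folds (default 10).
#' @param metric See [select_config()].
#' @param seed Integer seed for the fold assignment.
#' @return Object of class `svm_hyperparams`: list with `C`, `gamma`, and
#'   the internal `cv_accuracy` of the chosen pair.
#' @export
tune_rbf_svm <- function(X, y, C_grid = 2^seq(-5, 15, by = 2),
                         gamma_grid = 2^seq(-15, 3, by = 2),
                         n_folds = 10, metric = "accuracy", seed = 1) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  stopifnot(nlevels(y) == 2)
  n_folds <- min(n_folds, min(table(y)))
  folds <- stratified_folds(y, n_folds, seed = derive_seed(seed, "tunefolds"))
  grid <- expand.grid(gamma = sort(gamma_grid), C = sort(C_grid))
  grid <- grid[order(grid$C, grid$gamma), ]
  best <- list(C = NA_real_, gamma = NA_real_, cv_accuracy = -Inf)
  for (gi in seq_len(nrow(grid))) {
    scores <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2 || !any(!tr)) return(NA_real_)
      prm <- scaling_params(X[tr, , drop = FALSE])
      fit <- e1071::svm(apply_scaling(X[tr, , drop = FALSE], prm), y[tr],
                        kernel = "radial", cost = grid$C[gi],
                        gamma = grid$gamma[gi], scale = FALSE)
      pred <- stats::predict(fit, apply_scaling(X[!tr, , drop = FALSE], prm))
      prediction_score(y[!tr], pred, metric)
    }, numeric(1))
    acc <- mean(scores, na.rm = TRUE)
    if (acc > best$cv_accuracy + 1e-12) {
      best <- list(C = grid$C[gi], gamma = grid$gamma[gi], cv_accuracy = acc)
    }
  }
  structure(best, class = "svm_hyperparams")
}

#' Externally cross-validated accuracy vs. number of top features
#'
#' Estimates generalization accuracy as a function of the number of top
#' features, with feature ranking *external* to each hold-out fold so the
#' estimate is unbiased by selection: within each stratified fold, features
#' are ranked by [msvm_rfe_rank()] on the training portion only; for each
#' `k` in the grid an RBF-SVM is tuned (internal cross-validation) and
#' trained on the top-`k` training features and scored on the held-out
#' portion. Fold scores are averaged per `k`.
#'
#' @param X Observations x features matrix (n >= 20 recommended).
#' @param y Two-class factor, both classes present in every fold.
#' @param cfg A [select_config()].
#' @return Object of class `cv_curve`: data frame with columns `k` and
#'   `accuracy`, with the per-fold score matrix in attribute
#'   `"fold_scores"`.
#' @export
external_cv_curve <- function(X, y, cfg = select_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  y <- droplevels(as.factor(y))
  stopifnot(nlevels(y) == 2)
  k_grid <- cfg$k_grid %||% default_k_grid(ncol(X))
  if (any(k_grid > ncol(X))) {
    warning("k values above the feature count truncated")
    k_grid <- unique(pmin(k_grid, ncol(X)))
  }
  k_grid <- sort(unique(as.integer(k_grid)))
  folds <- stratified_folds(y, cfg$n_folds, seed = derive_seed(cfg$seed, "cvfolds"))
  scores <- matrix(NA_real_, cfg$n_folds, length(k_grid),
                   dimnames = list(NULL, paste0("k", k_grid)))
  for (f in seq_len(cfg$n_folds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2 || !any(!tr)) next
    fold_rfe <- cfg$rfe
    fold_rfe$seed <- derive_seed(cfg$seed, paste0("rank/fold", f))
    ranked <- msvm_rfe_rank(X[tr, , drop = FALSE], y[tr], fold_rfe)
    for (ki in seq_along(k_grid)) {
      feats <- ranked$ranking[seq_len(k_grid[ki])]
      hp <- tune_rbf_svm(X[tr, feats, drop = FALSE], y[tr],
                         C_grid = cfg$C_grid, gamma_grid = cfg$gamma_grid,
                         n_folds = cfg$tune_folds, metric = cfg$metric,
                         seed = derive_seed(cfg$seed, sprintf("tune/f%d/k%d", f, k_grid[ki])))
      prm <- scaling_params(X[tr, feats, drop = FALSE])
      fit <- e1071::svm(apply_scaling(X[tr, feats, drop = FALSE], prm), y[tr],
                        kernel = "radial", cost = hp$C, gamma = hp$gamma,
                        scale = FALSE)
      pred <- stats::predict(fit, apply_scaling(X[!tr, feats, drop = FALSE], prm))
      scores[f, ki] <- prediction_score(y[!tr], pred, cfg$metric)
    }
  }
  curve <- data.frame(k = k_grid, accuracy = colMeans(scores, na.rm = TRUE))
  attr(curve, "fold_scores") <- scores
  class(curve) <- c("cv_curve", "data.frame")
  curve
}

#' Select the optimal number of top features from a CV curve
#'
#' The number of features attaining the maximum mean hold-out accuracy
#' (equivalently the minimum error along the curve); ties resolve to the
#' smallest `k`.
#'
#' @param curve A `cv_curve` from [external_cv_curve()].
#' @return List with `k` (the chosen size) and `expected_accuracy`.
#' @export
select_optimal_k <- function(curve) {
  stopifnot(nrow(curve) >= 1)
  best <- which.max(curve$accuracy)  # first maximum = smallest k (k sorted)
  list(k = curve$k[best], expected_accuracy = curve$accuracy[best])
}
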