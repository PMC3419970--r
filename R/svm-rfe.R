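#' Configuration for (m)SVM-RFE feature ranking
#'
#' @param C Soft-margin penalty for the linear SVM ranking fits (default 1).
#' @param n_subsamples Number of stratified subsamples per elimination pass
#'   for the multiple-subsample criterion (default 10).
#' @param subsample_fraction Fraction of observations per subsample
#'   (default 0.9, sampled without replacement, stratified by class).
#' @param drop_half_threshold While more features than this survive, half of
#'   them are eliminated per pass; below it the algorithm switches to
#'   one-by-one elimination (default 5000).
#' @param seed Integer seed making the subsampling deterministic.
#' @return An object of class `rfe_config`.
#' @export
rfe_config <- function(C = 1, n_subsamples = 10, subsample_fraction = 0.9,
                       drop_half_threshold = 5000, seed = 1) {
  if (C <= 0) stop("C must be positive")
  if (n_subsamples < 1) stop("n_subsamples must be >= 1")
  if (!(subsample_fraction > 0 && subsample_fraction <= 1)) {
    stop("subsample_fraction must be in (0, 1]")
  }
  structure(list(C = C, n_subsamples = as.integer(n_subsamples),
                 subsample_fraction = subsample_fraction,
                 drop_half_threshold = drop_half_threshold,
                 seed = as.integer(seed)),
            class = "rfe_config")
}

#' Linear SVM feature weights
#'
#' Fits a soft-margin linear SVM (Cortes--Vapnik) on features standardized
#' to mean 0 / sd 1 over the observations passed in (and only those), and
#' returns the primal weight vector, one weight per feature. The magnitude
#' of these weights is the feature-usefulness criterion for recursive
#' feature elimination.
#'
#' @param X Numeric matrix or data frame, observations x features.
#' @param y Two-class factor with at least 2 observations per class.
#' @param C Soft-margin penalty.
#' @return Named numeric weight vector.
#' @export
linear_svm_weights <- function(X, y, C = 1) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("y must have exactly 2 classes")
  if (min(table(y)) < 2) stop("need at least 2 observations per class")
  if (any(!is.finite(X))) stop("non-finite feature values")
  prm <- scaling_params(X)
  Xs <- apply_scaling(X, prm)
  fit <- e1071::svm(Xs, y, kernel = "linear", cost = C, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  names(w) <- colnames(X)
  w
}

#' Elimination schedule of SVM-RFE
#'
#' Survivor counts at the start of each elimination pass: halving while more
#' than `drop_half_threshold` features remain, then one-by-one down to a
#' single top feature.
#'
#' @param n_features Starting feature count.
#' @param drop_half_threshold Switch point between halving and one-by-one.
#' @return Integer vector of pass sizes (first element `n_features`, last 2).
#' @export
rfe_schedule <- function(n_features, drop_half_threshold = 5000) {
  n <- as.integer(n_features)
  sizes <- integer(0)
  while (n > 1) {
    sizes <- c(sizes, n)
    n <- if (n > drop_half_threshold) n - floor(n / 2) else n - 1L
  }
  sizes
}

rank_from_elimination <- function(eliminated, survivor) {
  ranking <- rev(c(eliminated, survivor))
  structure(list(ranking = ranking), class = "ranked_features")
}

# shared elimination engine; criterion_fun(X_surv, y, pass) -> numeric vector
rfe_engine <- function(X, y, cfg, criterion_fun) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  if (any(!is.finite(X))) stop("non-finite feature values")
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("y must have exactly 2 classes")
  if (ncol(X) < 2) stop("need at least 2 features")
  surv <- colnames(X)
  eliminated <- character(0)
  pass_sizes <- integer(0)
  pass <- 0L
  while (length(surv) > 1) {
    pass <- pass + 1L
    pass_sizes <- c(pass_sizes, length(surv))
    crit <- criterion_fun(X[, surv, drop = FALSE], y, pass)
    n <- length(surv)
    n_drop <- if (n > cfg$drop_half_threshold) floor(n / 2) else 1L
    # ties in the criterion break by original column order: among ties the
    # later column is eliminated first, so earlier columns rank better
    orig <- match(surv, colnames(X))
    ord <- order(crit, -orig)
    drop_idx <- ord[seq_len(n_drop)]
    eliminated <- c(eliminated, surv[drop_idx])
    surv <- surv[-drop_idx]
  }
  out <- rank_from_elimination(eliminated, surv)
  out$pass_sizes <- pass_sizes
  out$feature_names <- colnames(X)
  out
}

#' SVM-RFE feature ranking (single-fit criterion)
#'
#' Recursive feature elimination: on each pass a linear SVM is refit on the
#' surviving features and the features with the smallest squared weights are
#' eliminated -- half of the survivors while more than
#' `cfg$drop_half_threshold` remain, then one feature at a time. Eliminated
#' features are never reconsidered; rank 1 is the last survivor.
#'
#' @param X Observations x features matrix.
#' @param y Two-class factor.
#' @param cfg An [rfe_config()].
#' @return Object of class `ranked_features`: list with `ranking` (feature
#'   names, rank 1 first -- a permutation of the input names), `pass_sizes`
#'   (survivor count at each pass), and `feature_names`.
#' @export
svm_rfe_rank <- function(X, y, cfg = rfe_config()) {
  rfe_engine(X, y, cfg, function(Xs, ys, pass) {
    linear_svm_weights(Xs, ys, cfg$C)^2
  })
}

# stratified row subsample; redraws with an incremented seed if a class is
# lost (logged via message)
stratified_subsample <- function(y, fraction, seed) {
  n <- length(y)
  for (try in 0:20) {
    idx <- with_seed(seed + try, {
      unlist(lapply(levels(y), function(cl) {
        rows <- which(y == cl)
        take <- max(1L, round(fraction * length(rows)))
        sample(rows, take)
      }), use.names = FALSE)
    })
    if (length(unique(y[idx])) == 2 && min(table(y[idx])) >= 2) {
      if (try > 0) message("subsample redrawn ", try, " time(s) to keep both classes")
      return(sort(idx))
    }
  }
  stop("could not draw a two-class subsample")
}

#' Multiple SVM-RFE feature ranking (subsample-stabilized criterion)
#'
#' SVM-RFE with a resampling layer on every elimination pass: `n_subsamples`
#' linear SVMs are fit on stratified subsamples of the observations and the
#' per-feature criterion is the mean of the squared weights across
#' subsamples divided by its standard deviation, which rewards features
#' whose usefulness is both large and stable. The elimination schedule is
#' that of [svm_rfe_rank()]. With `n_subsamples = 1` and
#' `subsample_fraction = 1` the ranking reduces exactly to [svm_rfe_rank()].
#' Deterministic given `cfg$seed`.
#'
#' @inheritParams svm_rfe_rank
#' @return Object of class `ranked_features` (see [svm_rfe_rank()]).
#' @export
msvm_rfe_rank <- function(X, y, cfg = rfe_config()) {
  single <- cfg$n_subsamples == 1 && cfg$subsample_fraction >= 1
  rfe_engine(X, y, cfg, function(Xs, ys, pass) {
    if (single) {
      return(linear_svm_weights(Xs, ys, cfg$C)^2)
    }
    W2 <- matrix(NA_real_, cfg$n_subsamples, ncol(Xs))
    for (b in seq_len(cfg$n_subsamples)) {
      sseed <- derive_seed(cfg$seed, sprintf("pass%d/sub%d", pass, b))
      idx <- stratified_subsample(ys, cfg$subsample_fraction, sseed)
      W2[b, ] <- linear_svm_weights(Xs[idx, , drop = FALSE], ys[idx], cfg$C)^2
    }
    mu <- colMeans(W2)
    sigma <- apply(W2, 2, stats::sd)
    mu / pmax(sigma, .Machine$double.eps)
  })
}
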