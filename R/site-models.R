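#' Train a site- and modality-specific RBF-SVM classifier
#'
#' Fits the final classifier for one site and one feature modality on *all*
#' supplied observations, using only the top `k` features of a ranked list,
#' standardized by the site's own training statistics. The model carries its
#' selected feature names, scaler, hyperparameters, class priors and
#' (optionally) site subtype priors, and predicts only from its selected
#' features.
#'
#' @param X Observations x features matrix for the site.
#' @param y Two-class factor (`TD` vs `ADHD`); both classes must be present
#'   -- a single-class site must go through the across-site alignment path.
#' @param ranked A `ranked_features` object (or character vector of feature
#'   names, best first).
#' @param k Number of top features to use (`k <=` available features).
#' @param hyperparams An `svm_hyperparams` object, or `NULL` to tune on the
#'   training data via [tune_rbf_svm()].
#' @param site,modality Identifiers stored on the model.
#' @param subtype_priors Optional named vector of site ADHD-subtype counts.
#' @param seed Seed used when tuning.
#' @return Object of class `adhd_site_model`.
#' @export
train_site_model <- function(X, y, ranked, k, hyperparams = NULL,
                             site = "site", modality = "modality",
                             subtype_priors = NULL, seed = 1) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) {
    stop("site training data contain a single class; use the across-site ",
         "alignment path (align_sites_by_td / align_sites_unlabeled)")
  }
  ranking <- if (inherits(ranked, "ranked_features")) ranked$ranking else as.character(ranked)
  if (k > length(ranking)) stop("k exceeds the number of ranked features")
  feats <- ranking[seq_len(k)]
  missing <- setdiff(feats, colnames(X))
  if (length(missing)) stop("features absent from X: ", paste(missing, collapse = ", "))
  Xs <- X[, feats, drop = FALSE]
  if (is.null(hyperparams)) hyperparams <- tune_rbf_svm(Xs, y, seed = seed)
  prm <- scaling_params(Xs)
  fit <- e1071::svm(apply_scaling(Xs, prm), y, kernel = "radial",
                    cost = hyperparams$C, gamma = hyperparams$gamma,
                    scale = FALSE)
  structure(list(
    site = site, modality = modality, features = feats,
    center = prm$center, scale = prm$scale,
    medians = apply(Xs, 2, stats::median),
    hyperparams = hyperparams,
    class_priors = prop.table(table(y)),
    subtype_priors = subtype_priors,
    levels = levels(y), fit = fit
  ), class = "adhd_site_model")
}

#' Predict diagnosis with a trained site model
#'
#' @param object An `adhd_site_model`.
#' @param newdata Matrix or data frame containing the model's selected
#'   feature columns.
#' @param impute If `TRUE`, feature columns missing from `newdata` (or `NA`
#'   cells) are filled with the training medians; otherwise a missing
#'   column is an error naming the column.
#' @param ... Unused.
#' @return Factor of predicted two-class labels, one per row.
#' @export
predict.adhd_site_model <- function(object, newdata, impute = FALSE, ...) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing) && !impute) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  }
  for (mcol in missing) newdata[[mcol]] <- object$medians[[mcol]]
  Xn <- as.matrix(newdata[, object$features, drop = FALSE])
  if (anyNA(Xn)) {
    if (!impute) stop("NA feature values; set impute = TRUE to use training medians")
    for (j in seq_along(object$features)) {
      Xn[is.na(Xn[, j]), j] <- object$medians[[object$features[j]]]
    }
  }
  Xn <- sweep(sweep(Xn, 2, object$center, "-"), 2, object$scale, "/")
  stats::predict(object$fit, Xn)
}

align_input_matrices <- function(X_by_site) {
  stopifnot(is.list(X_by_site), length(X_by_site) >= 1)
  cols <- colnames(X_by_site[[1]])
  lapply(X_by_site, function(Xi) {
    Xi <- as.matrix(Xi)
    if (!identical(colnames(Xi), cols)) stop("sites must share identical feature columns")
    Xi
  })
}

#' Align site feature distributions on their typically-developing subgroup
#'
#' Sites that lack (complete) labeled training data can still be classified
#' by an across-site model once nuisance site offsets are removed. For every
#' feature and site, the site's TD mean is subtracted and the pooled TD mean
#' (over all sites) added, so after adjustment every site's TD mean equals
#' the pooled TD mean exactly while within-site class contrasts are
#' untouched (a pure per-site shift). A site with no TD subjects falls back
#' to the cruder unlabeled alignment (its grand mean is mapped to the pooled
#' TD mean). With `align_variance = TRUE` the per-site TD standard
#' deviations are also rescaled to the pooled TD value (off by default).
#'
#' @param X_by_site Named list of site feature matrices with identical
#'   columns.
#' @param td_by_site Named list of logical vectors flagging the TD rows of
#'   each site.
#' @param align_variance Also match TD standard deviations (default `FALSE`).
#' @return Named list of adjusted matrices, same shapes as the input.
#' @export
align_sites_by_td <- function(X_by_site, td_by_site, align_variance = FALSE) {
  Xs <- align_input_matrices(X_by_site)
  stopifnot(identical(names(Xs), names(td_by_site)))
  td_rows <- do.call(rbind, Map(function(Xi, td) Xi[td, , drop = FALSE], Xs, td_by_site))
  if (nrow(td_rows) < 2) stop("need at least 2 TD subjects overall")
  pooled_mean <- colMeans(td_rows)
  pooled_sd <- apply(td_rows, 2, stats::sd)
  out <- Map(function(Xi, td) {
    ref <- if (any(td)) Xi[td, , drop = FALSE] else Xi
    site_mean <- colMeans(ref)
    adj <- sweep(Xi, 2, site_mean, "-")
    if (align_variance && sum(td) >= 2) {
      site_sd <- apply(ref, 2, stats::sd)
      ratio <- ifelse(site_sd > 0, pooled_sd / site_sd, 1)
      adj <- sweep(adj, 2, ratio, "*")
    }
    sweep(adj, 2, pooled_mean, "+")
  }, Xs, td_by_site)
  names(out) <- names(Xs)
  out
}

#' Align site feature distributions without labels
#'
#' For a site with no training labels at all, the per-feature bias
#' adjustment must be based on all its subjects together: each site's grand
#' mean is subtracted and the pooled grand mean added. When the class mix is
#' equal across sites this coincides with the TD alignment up to the common
#' class-mix offset.
#'
#' @param X_by_site Named list of site feature matrices with identical
#'   columns.
#' @return Named list of adjusted matrices.
#' @export
align_sites_unlabeled <- function(X_by_site) {
  Xs <- align_input_matrices(X_by_site)
  all_rows <- do.call(rbind, Xs)
  pooled_mean <- colMeans(all_rows)
  out <- lapply(Xs, function(Xi) {
    if (nrow(Xi) < 2) stop("each site needs at least 2 subjects")
    sweep(sweep(Xi, 2, colMeans(Xi), "-"), 2, pooled_mean, "+")
  })
  names(out) <- names(Xs)
  out
}
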