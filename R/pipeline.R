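#' Feature matrices for every modality of a synthetic cohort
#'
#' Computes the per-subject feature matrix of each requested modality:
#' `demographics` (age, gender, IQ; IQ stays `NA` at sites that do not
#' measure it), `connectivity` (lower-triangle Fisher-z edges),
#' `power` (one-sided amplitude spectrum per ROI and frequency bin),
#' `graph` (global and nodal network metrics averaged across sparsity
#' levels), `morphometry` (the 747-column structural battery), and -- when
#' the cohort carries voxel data -- `reho` and `gcor` (voxelwise regional
#' homogeneity and global connectivity).
#'
#' @param cohort An `adhd_cohort` from [generate_cohort()].
#' @param modalities Character vector of modality names.
#' @param graph_levels,graph_mode,graph_n_random Options passed to
#'   [metrics_across_sparsities()] for the `graph` modality.
#' @param seed Seed for the graph normalization ensembles.
#' @return Named list of subjects x features matrices (subject ids as row
#'   names).
#' @export
cohort_feature_matrices <- function(cohort,
                                    modalities = c("demographics", "connectivity",
                                                   "power", "morphometry"),
                                    graph_levels = c(0.10, 0.15, 0.20, 0.25, 0.30),
                                    graph_mode = "weighted",
                                    graph_n_random = 100,
                                    seed = 1) {
  ph <- cohort$phenotypes
  ids <- ph$subject_id
  out <- list()
  for (mod in modalities) {
    X <- switch(mod,
      demographics = {
        m <- cbind(age = ph$age, gender_m = as.numeric(ph$gender == "M"),
                   iq = ph$iq)
        rownames(m) <- ids
        m
      },
      connectivity = {
        t(vapply(ids, function(id) {
          vectorize_connectivity(connectivity_matrix(cohort$timeseries[[id]]))
        }, numeric(cohort$config$n_roi * (cohort$config$n_roi - 1) / 2)))
      },
      power = {
        t(vapply(ids, function(id) {
          ps <- power_spectrum(cohort$timeseries[[id]], TR = cohort$config$TR)
          v <- as.vector(ps$amplitude)
          names(v) <- as.vector(outer(rownames(ps$amplitude),
                                      colnames(ps$amplitude),
                                      function(f, r) paste(r, f, sep = "__")))
          v
        }, numeric((floor(cohort$config$n_timepoints / 2) + 1) * cohort$config$n_roi)))
      },
      graph = {
        t(vapply(ids, function(id) {
          m <- connectivity_matrix(cohort$timeseries[[id]])
          metrics_across_sparsities(m, levels = graph_levels, mode = graph_mode,
                                    n_random = graph_n_random,
                                    seed = derive_seed(seed, paste0("graph/", id)))
        }, numeric(length(metric_names_for(cohort$config$n_roi, graph_n_random)))))
      },
      morphometry = {
        m <- as.matrix(cohort$morphometry[, morphometry_feature_names()])
        rownames(m) <- cohort$morphometry$subject_id
        m[ids, , drop = FALSE]
      },
      reho = {
        stopifnot(!is.null(cohort$voxels))
        t(vapply(ids, function(id) {
          voxel_map_features(regional_homogeneity(cohort$voxels[[id]],
                                                  cohort$voxel_mask), "reho")
        }, numeric(sum(cohort$voxel_mask))))
      },
      gcor = {
        stopifnot(!is.null(cohort$voxels))
        t(vapply(ids, function(id) {
          voxel_map_features(global_connectivity(cohort$voxels[[id]],
                                                 cohort$voxel_mask), "gcor")
        }, numeric(sum(cohort$voxel_mask))))
      },
      stop("unknown modality: ", mod)
    )
    out[[mod]] <- X
  }
  out
}

metric_names_for <- function(n_roi, n_random) {
  glob <- c("global_cc", "global_eloc", "global_cpl", "global_eglob", "global_q")
  if (n_random > 0) glob <- c(glob, "global_gamma", "global_lambda", "global_sigma")
  c(glob, as.vector(vapply(c("strength", "cc", "eloc", "ereg", "bc"),
                           function(m) paste0("nodal_", m, "_", roi_names(n_roi)),
                           character(n_roi))))
}

#' Configuration of an end-to-end pipeline run
#'
#' Bundles the cohort configuration and every stage parameter: modalities,
#' train/test split, the feature-ranking and subset-selection settings, the
#' hyperparameter grids, the graph options, the vote tie rule and the point
#' scheme. All randomized stages derive named seeds from `seed`, so a run
#' is fully reproducible from its configuration.
#'
#' @param cohort A [cohort_config()].
#' @param modalities Modalities to classify with (see
#'   [cohort_feature_matrices()]).
#' @param combined Also train, per site, a model on the union of the
#'   selected features of all modalities (default `TRUE`).
#' @param test_fraction Held-out fraction per site (stratified by class).
#' @param n_folds,tune_folds External / internal cross-validation folds.
#' @param k_grid Numbers of top features to evaluate.
#' @param rfe An [rfe_config()] for feature ranking. The default uses a
#'   reduced half-dropping threshold suited to the feature counts of the
#'   synthetic cohorts.
#' @param C_grid,gamma_grid RBF-SVM hyperparameter grids.
#' @param graph_levels,graph_mode,graph_n_random Graph-modality options.
#' @param vote_tie Tie rule of the final vote (default `"TD"`).
#' @param points_scheme Point scheme for [score_predictions()].
#' @param exclude_sites Sites dropped entirely before any fitting.
#' @param seed Master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort,
                            modalities = c("demographics", "connectivity",
                                           "morphometry"),
                            combined = TRUE,
                            test_fraction = 0.3,
                            n_folds = 5,
                            tune_folds = 5,
                            k_grid = c(1, 2, 5, 10, 25, 50),
                            rfe = rfe_config(n_subsamples = 5,
                                             drop_half_threshold = 64),
                            C_grid = 2^seq(-3, 7, by = 2),
                            gamma_grid = 2^seq(-9, 1, by = 2),
                            graph_levels = c(0.10, 0.15, 0.20, 0.25, 0.30),
                            graph_mode = "weighted",
                            graph_n_random = 20,
                            vote_tie = "TD",
                            points_scheme = c(correct_td = 1, correct_subtype = 1,
                                              wrong_subtype = 0.5, wrong = 0),
                            exclude_sites = character(),
                            seed = 1) {
  stopifnot(inherits(cohort, "cohort_config"))
  structure(list(cohort = cohort, modalities = modalities, combined = combined,
                 test_fraction = test_fraction, n_folds = n_folds,
                 tune_folds = tune_folds, k_grid = k_grid, rfe = rfe,
                 C_grid = C_grid, gamma_grid = gamma_grid,
                 graph_levels = graph_levels, graph_mode = graph_mode,
                 graph_n_random = graph_n_random, vote_tie = vote_tie,
                 points_scheme = points_scheme, exclude_sites = exclude_sites,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

site_usable_columns <- function(X, rows) {
  ok <- colSums(is.na(X[rows, , drop = FALSE])) == 0
  colnames(X)[ok]
}

#' Run the full classification pipeline on a synthetic cohort
#'
#' Executes every stage in order: cohort generation, ADHD-H and excluded-site
#' removal, a stratified per-site train/test split, feature extraction per
#' modality, per-site mSVM-RFE feature ranking, externally cross-validated
#' selection of the optimal number of top features, nested hyperparameter
#' tuning, training of the final per-site per-modality RBF-SVMs (plus an
#' all-modalities-combined model on the union of selected features), an
#' across-site TD-aligned model for sites whose training data contain a
#' single class, majority voting across modalities, site-specific subtype
#' assignment, and competition-style scoring against the held-out truth.
#' Identical configurations (including seed) give identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory; when given, predictions, CV curves,
#'   the score report and a JSON run log (all seeds and stage parameters)
#'   are written there.
#' @return List with `score` (a `score_report`), `predictions` (data frame
#'   with one vote column per modality, `final_label` and three-class
#'   `label`), `curves`, `selected` (per site/modality `k*` and expected
#'   accuracy), `models`, and the generated `cohort`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  cohort_cfg <- cfg$cohort
  cohort_cfg$seed <- derive_seed(cfg$seed, "cohort")
  cohort <- generate_cohort(cohort_cfg)

  ph <- cohort$phenotypes
  keep <- ph$dx != "ADHD-H" & !(ph$site %in% cfg$exclude_sites)
  ph <- ph[keep, , drop = FALSE]

  # stratified per-site train/test split
  is_test <- logical(nrow(ph))
  for (s in unique(ph$site)) {
    for (cl in unique(ph$dx[ph$site == s])) {
      rows <- which(ph$site == s & ph$dx == cl)
      n_test <- round(cfg$test_fraction * length(rows))
      if (n_test > 0) {
        pick <- with_seed(derive_seed(cfg$seed, paste0("split/", s, "/", cl)),
                          sample(rows, n_test))
        is_test[pick] <- TRUE
      }
    }
  }
  train_ph <- ph[!is_test, , drop = FALSE]
  test_ph <- ph[is_test, , drop = FALSE]

  feats <- cohort_feature_matrices(cohort, cfg$modalities,
                                   graph_levels = cfg$graph_levels,
                                   graph_mode = cfg$graph_mode,
                                   graph_n_random = cfg$graph_n_random,
                                   seed = derive_seed(cfg$seed, "features"))
  feats <- lapply(feats, function(X) X[ph$subject_id, , drop = FALSE])

  y2 <- collapse_dx(ph$dx)
  names(y2) <- ph$subject_id

  sites <- unique(ph$site)
  curves <- list(); models <- list(); selected <- list()
  votes <- data.frame(subject_id = test_ph$subject_id, site = test_ph$site,
                      stringsAsFactors = FALSE)

  for (s in sites) {
    tr_ids <- train_ph$subject_id[train_ph$site == s]
    te_ids <- test_ph$subject_id[test_ph$site == s]
    if (length(te_ids) == 0) next
    two_class <- length(tr_ids) > 0 && nlevels(droplevels(y2[tr_ids])) == 2
    site_features <- list()
    for (mod in cfg$modalities) {
      key <- paste(s, mod, sep = "/")
      X <- feats[[mod]]
      if (two_class) {
        usable <- site_usable_columns(X, tr_ids)
        if (length(usable) < 2) next
        Xtr <- X[tr_ids, usable, drop = FALSE]
        ytr <- droplevels(y2[tr_ids])
        sel_cfg <- select_config(
          n_folds = cfg$n_folds,
          k_grid = sort(unique(pmin(cfg$k_grid, length(usable)))),
          rfe = cfg$rfe, C_grid = cfg$C_grid, gamma_grid = cfg$gamma_grid,
          tune_folds = cfg$tune_folds,
          seed = derive_seed(cfg$seed, paste0("select/", key)))
        curve <- external_cv_curve(Xtr, ytr, sel_cfg)
        kopt <- select_optimal_k(curve)
        rfe_full <- cfg$rfe
        rfe_full$seed <- derive_seed(cfg$seed, paste0("rank/", key))
        ranked <- msvm_rfe_rank(Xtr, ytr, rfe_full)
        hp <- tune_rbf_svm(Xtr[, ranked$ranking[seq_len(kopt$k)], drop = FALSE],
                           ytr, C_grid = cfg$C_grid, gamma_grid = cfg$gamma_grid,
                           n_folds = cfg$tune_folds,
                           seed = derive_seed(cfg$seed, paste0("tune/", key)))
        model <- train_site_model(Xtr, ytr, ranked, kopt$k, hp, site = s,
                                  modality = mod)
        pred <- predict(model, X[te_ids, usable, drop = FALSE])
        curves[[key]] <- curve
        selected[[key]] <- data.frame(site = s, modality = mod, k = kopt$k,
                                      expected_accuracy = kopt$expected_accuracy)
        site_features[[mod]] <- model$features
      } else {
        # across-site path: align on TD (or grand) means, train on the
        # labeled sites' aligned data, predict this site's aligned rows
        res <- across_site_predict(s, mod, X, ph, train_ph, y2, te_ids, cfg)
        if (is.null(res)) next
        pred <- res$pred
        model <- res$model
        site_features[[mod]] <- model$features
      }
      models[[key]] <- model
      votes[votes$site == s, paste0("vote_", mod)] <- as.character(pred)[
        match(votes$subject_id[votes$site == s], te_ids)]
    }
    if (cfg$combined && two_class && length(site_features) >= 2) {
      union_feats <- unique(unlist(site_features, use.names = FALSE))
      X_all <- do.call(cbind, lapply(cfg$modalities, function(mod) {
        feats[[mod]][, intersect(colnames(feats[[mod]]), union_feats), drop = FALSE]
      }))
      ytr <- droplevels(y2[tr_ids])
      hp <- tune_rbf_svm(X_all[tr_ids, , drop = FALSE], ytr,
                         C_grid = cfg$C_grid, gamma_grid = cfg$gamma_grid,
                         n_folds = cfg$tune_folds,
                         seed = derive_seed(cfg$seed, paste0("tune/", s, "/combined")))
      model <- train_site_model(X_all[tr_ids, , drop = FALSE], ytr,
                                colnames(X_all), ncol(X_all), hp,
                                site = s, modality = "combined")
      pred <- predict(model, X_all[te_ids, , drop = FALSE])
      models[[paste(s, "combined", sep = "/")]] <- model
      votes[votes$site == s, "vote_combined"] <- as.character(pred)[
        match(votes$subject_id[votes$site == s], te_ids)]
    }
  }

  vote_cols <- grep("^vote_", names(votes), value = TRUE)
  if (length(vote_cols) == 0) stop("no stage produced predictions")
  votes$final_label <- vapply(seq_len(nrow(votes)), function(i) {
    v <- unlist(votes[i, vote_cols], use.names = FALSE)
    majority_vote(v[!is.na(v)], tie = cfg$vote_tie)
  }, character(1))
  votes$label <- votes$final_label
  adhd_rows <- votes$final_label == "ADHD"
  if (any(adhd_rows)) {
    site_subtype <- vapply(unique(votes$site), assign_subtype,
                           character(1), phenotypes = train_ph)
    votes$label[adhd_rows] <- site_subtype[votes$site[adhd_rows]]
  }

  truth <- test_ph[, c("subject_id", "dx")]
  score <- score_predictions(
    data.frame(subject_id = votes$subject_id, label = votes$label),
    truth, points_scheme = cfg$points_scheme)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_phenotypes(ph, file.path(out_dir, "phenotypes.csv"))
    write_predictions(votes, file.path(out_dir, "predictions.csv"))
    for (key in names(curves)) {
      write_cv_curve(curves[[key]],
                     file.path(out_dir, paste0("curve_", gsub("/", "_", key), ".csv")))
    }
    write_score_report(score, file.path(out_dir, "score.json"))
    log <- list(seed = cfg$seed,
                stage_seeds = list(cohort = derive_seed(cfg$seed, "cohort"),
                                   features = derive_seed(cfg$seed, "features")),
                modalities = cfg$modalities, test_fraction = cfg$test_fraction,
                n_folds = cfg$n_folds, tune_folds = cfg$tune_folds,
                k_grid = cfg$k_grid,
                rfe = unclass(cfg$rfe), C_grid = cfg$C_grid,
                gamma_grid = cfg$gamma_grid, vote_tie = cfg$vote_tie,
                points_scheme = as.list(cfg$points_scheme),
                exclude_sites = cfg$exclude_sites)
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(score = score, predictions = votes, curves = curves,
       selected = do.call(rbind, selected), models = models, cohort = cohort)
}

# across-site classifier for a site whose training data lack a class:
# align all sites on TD means (grand means if this site has no labels),
# rank + train on the labeled sites' aligned rows, predict this site's rows
across_site_predict <- function(site, mod, X, ph, train_ph, y2, te_ids, cfg) {
  labeled_sites <- setdiff(unique(train_ph$site[collapse_dx(train_ph$dx) == "ADHD"]),
                           site)
  if (length(labeled_sites) == 0) return(NULL)
  part_sites <- c(labeled_sites, site)
  rows_by_site <- lapply(part_sites, function(s2) {
    if (s2 == site) {
      ph$subject_id[ph$site == s2]  # all rows: TD train rows + test rows
    } else {
      train_ph$subject_id[train_ph$site == s2]
    }
  })
  names(rows_by_site) <- part_sites
  usable <- Reduce(intersect, lapply(rows_by_site, function(ids) {
    site_usable_columns(X, ids)
  }))
  if (length(usable) < 2) return(NULL)
  X_by_site <- lapply(rows_by_site, function(ids) X[ids, usable, drop = FALSE])
  td_by_site <- lapply(part_sites, function(s2) {
    ids <- rows_by_site[[s2]]
    ids %in% ph$subject_id[collapse_dx(ph$dx) == "TD" &
                             ph$subject_id %in% train_ph$subject_id]
  })
  names(td_by_site) <- part_sites
  aligned <- if (any(td_by_site[[site]])) {
    align_sites_by_td(X_by_site, td_by_site)
  } else {
    align_sites_unlabeled(X_by_site)
  }
  Xtr <- do.call(rbind, aligned[labeled_sites])
  tr_ids <- unlist(rows_by_site[labeled_sites], use.names = FALSE)
  ytr <- droplevels(y2[tr_ids])
  if (nlevels(ytr) < 2) return(NULL)
  rfe_cfg <- cfg$rfe
  rfe_cfg$seed <- derive_seed(cfg$seed, paste0("xrank/", site, "/", mod))
  ranked <- msvm_rfe_rank(Xtr, ytr, rfe_cfg)
  k <- min(max(cfg$k_grid[cfg$k_grid <= length(usable)]), length(usable))
  hp <- tune_rbf_svm(Xtr[, ranked$ranking[seq_len(k)], drop = FALSE], ytr,
                     C_grid = cfg$C_grid, gamma_grid = cfg$gamma_grid,
                     n_folds = cfg$tune_folds,
                     seed = derive_seed(cfg$seed, paste0("xtune/", site, "/", mod)))
  model <- train_site_model(Xtr, ytr, ranked, k, hp, site = site, modality = mod)
  target <- aligned[[site]]
  pred <- predict(model, target[te_ids, , drop = FALSE])
  list(pred = pred, model = model)
}
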