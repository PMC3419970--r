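# On-disk formats: CSV for phenotypes, time series, connectivity matrices,
# feature matrices, rankings, curves and predictions; NIfTI for voxel data
# and maps; JSON for model metadata, score reports and run logs. Every
# writer/reader pair round-trips.

#' Read a phenotype CSV
#'
#' Expects columns `subject_id, site, dx, age, gender, iq, handedness`;
#' empty `iq` fields become `NA` (a missing marker, never 0). Unknown
#' diagnosis values and duplicate subject ids are errors naming the
#' offending value.
#'
#' @param path CSV path.
#' @return Typed phenotype data frame.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  need <- c("subject_id", "site", "dx", "age", "gender", "iq")
  miss <- setdiff(need, names(ph))
  if (length(miss)) stop("phenotype file lacks column(s): ", paste(miss, collapse = ", "))
  ph$iq <- as.numeric(ph$iq)
  dup <- ph$subject_id[duplicated(ph$subject_id)]
  if (length(dup)) stop("duplicate subject_id: ", paste(unique(dup), collapse = ", "))
  bad <- !ph$dx %in% dx_levels()
  if (any(bad)) {
    stop("unknown dx value(s) at line(s) ", paste(which(bad) + 1, collapse = ", "),
         ": ", paste(unique(ph$dx[bad]), collapse = ", "))
  }
  ph$dx <- factor(ph$dx, levels = dx_levels())
  ph
}

#' Write a phenotype CSV
#'
#' @param phenotypes Phenotype data frame.
#' @param path Output path. Missing IQ is written as an empty field.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, na = "")
}

#' Read / write ROI time series CSV (T rows x R columns, ROI-name header)
#'
#' @param path CSV path.
#' @return Numeric matrix.
#' @export
read_timeseries_csv <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}

#' @rdname read_timeseries_csv
#' @param ts T x R matrix with ROI column names.
#' @export
write_timeseries_csv <- function(ts, path) {
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
}

#' Read / write a connectivity matrix as a square CSV
#'
#' The full square matrix is stored (human-inspectable) although only the
#' lower triangle feeds features.
#'
#' @param path CSV path.
#' @return A `connectivity_matrix`.
#' @export
read_connectivity_csv <- function(path) {
  z <- as.matrix(utils::read.csv(path, check.names = FALSE))
  as_connectivity_matrix(z, colnames(z))
}

#' @rdname read_connectivity_csv
#' @param m A `connectivity_matrix`.
#' @export
write_connectivity_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m$z), path, row.names = FALSE)
}

#' Read / write a subjects x features matrix CSV
#'
#' First column `subject_id`, remaining columns are features.
#'
#' @param path CSV path.
#' @return Numeric matrix with subject ids as row names.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_feature_matrix
#' @param X Matrix with subject ids as row names.
#' @export
write_feature_matrix <- function(X, path) {
  df <- data.frame(subject_id = rownames(X), as.data.frame(X),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Read / write a ranked feature list as a two-column CSV (rank, feature)
#'
#' @param path CSV path.
#' @return A `ranked_features` object.
#' @export
read_ranked_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(list(ranking = df$feature[order(df$rank)]),
            class = "ranked_features")
}

#' @rdname read_ranked_list
#' @param ranked A `ranked_features` object.
#' @export
write_ranked_list <- function(ranked, path) {
  utils::write.csv(data.frame(rank = seq_along(ranked$ranking),
                              feature = ranked$ranking),
                   path, row.names = FALSE)
}

#' Write a cross-validation curve CSV
#'
#' @param curve A `cv_curve`.
#' @param path Output path.
#' @export
write_cv_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
}

#' Read / write predictions CSV
#'
#' Columns: `subject_id`, `site`, one `vote_<modality>` column per
#' contributing model, `final_label` (two-class) and `label` (three-class).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_predictions <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_predictions
#' @param pred Predictions data frame.
#' @export
write_predictions <- function(pred, path) {
  utils::write.csv(pred, path, row.names = FALSE)
}

#' Read / write 4-D voxel data and 3-D masks/maps as NIfTI
#'
#' @param path NIfTI path (`.nii` / `.nii.gz`).
#' @return Numeric array.
#' @export
read_nifti_array <- function(path) {
  a <- RNifti::readNifti(path)
  array(as.numeric(a), dim = dim(a))
}

#' @rdname read_nifti_array
#' @param arr 3-D or 4-D numeric/logical array (masks are written strictly
#'   binary).
#' @param pixdim Voxel dimensions (mm / s) for the header.
#' @export
write_nifti_array <- function(arr, path, pixdim = rep(1, length(dim(arr)))) {
  if (is.logical(arr)) arr <- array(as.numeric(arr), dim = dim(arr))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- pixdim
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Save / load a trained site model
#'
#' The model's metadata (site, modality, selected features, scaler, priors,
#' hyperparameters) is written as JSON next to an opaque RDS blob holding
#' the fitted classifier state.
#'
#' @param model An `adhd_site_model`.
#' @param path Path of the JSON file; the blob is stored at `<path>.rds`.
#' @return `path`, invisibly.
#' @export
save_site_model <- function(model, path) {
  meta <- list(
    site = model$site, modality = model$modality, features = model$features,
    center = as.list(model$center), scale = as.list(model$scale),
    medians = as.list(model$medians),
    hyperparams = list(C = model$hyperparams$C, gamma = model$hyperparams$gamma),
    class_priors = as.list(model$class_priors),
    subtype_priors = as.list(model$subtype_priors),
    state_blob = paste0(basename(path), ".rds")
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  saveRDS(model, paste0(path, ".rds"))
  invisible(path)
}

#' @rdname save_site_model
#' @export
load_site_model <- function(path) {
  readRDS(paste0(path, ".rds"))
}

#' Write a score report as JSON
#'
#' @param report A `score_report`.
#' @param path Output path.
#' @export
write_score_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
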