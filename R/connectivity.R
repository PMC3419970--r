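#' Fisher z-transform of a correlation coefficient
#'
#' `atanh` of the correlation, with `|r|` capped at `r_max` first so that
#' perfect correlations map to a large finite value rather than infinity.
#'
#' @param r Numeric vector of correlations in `[-1, 1]`.
#' @param r_max Cap applied to `|r|` before `atanh` (default `1 - 1e-7`).
#' @return Numeric vector of Fisher-z values.
#' @export
fisher_z <- function(r, r_max = 1 - 1e-7) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must be <= 1")
  atanh(pmax(pmin(r, r_max), -r_max))
}

#' Fisher-z Pearson connectivity matrix from ROI time series
#'
#' Computes the R x R matrix of pairwise Pearson correlations between ROI
#' time series and Fisher z-transforms it. The diagonal is stored as 0 and
#' excluded from features. Constant columns cannot be correlated; their rows
#' and columns are set to 0 with a warning.
#'
#' @param ts T x R numeric matrix of ROI time series (T >= 3); column names
#'   are used as ROI names.
#' @param r_max Correlation cap passed to [fisher_z()].
#' @return An object of class `connectivity_matrix`: a list with `z` (R x R
#'   symmetric matrix) and `roi_names`.
#' @export
connectivity_matrix <- function(ts, r_max = 1 - 1e-7) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("need at least 3 time points")
  if (ncol(ts) < 2) stop("need at least 2 ROIs")
  rois <- colnames(ts) %||% roi_names(ncol(ts))
  sds <- apply(ts, 2, stats::sd)
  const <- sds == 0
  r <- suppressWarnings(stats::cor(ts))
  if (any(const)) {
    warning("constant ROI series zeroed in connectivity matrix: ",
            paste(rois[const], collapse = ", "))
    r[const, ] <- 0
    r[, const] <- 0
  }
  z <- fisher_z(r, r_max = r_max)
  diag(z) <- 0
  z <- (z + t(z)) / 2
  dimnames(z) <- list(rois, rois)
  structure(list(z = z, roi_names = rois), class = "connectivity_matrix")
}

#' Construct a connectivity matrix object from a Fisher-z matrix
#'
#' @param z Symmetric R x R matrix of Fisher-z values (diagonal ignored).
#' @param roi_names Optional ROI names.
#' @param tol Symmetry tolerance.
#' @return A `connectivity_matrix`.
#' @export
as_connectivity_matrix <- function(z, roi_names = NULL, tol = 1e-8) {
  z <- as.matrix(z)
  if (nrow(z) != ncol(z)) stop("z must be square")
  if (max(abs(z - t(z))) > tol) stop("z must be symmetric")
  rois <- roi_names %||% colnames(z) %||% sprintf("roi_%03d", seq_len(ncol(z)))
  diag(z) <- 0
  dimnames(z) <- list(rois, rois)
  structure(list(z = z, roi_names = rois), class = "connectivity_matrix")
}

#' Vectorize the lower triangle of a connectivity matrix
#'
#' The connectivity matrix is symmetric, so only the lower triangle is used
#' as machine-learning features: `R(R-1)/2` values, named
#' `"<roi_i>__<roi_j>"` with `i < j` in atlas order.
#'
#' @param m A `connectivity_matrix`.
#' @return Named numeric vector of length `R(R-1)/2`.
#' @export
vectorize_connectivity <- function(m) {
  stopifnot(inherits(m, "connectivity_matrix"))
  z <- m$z
  lt <- lower.tri(z)
  idx <- which(lt, arr.ind = TRUE)  # row > col, column-major order
  v <- z[lt]
  names(v) <- paste(m$roi_names[idx[, "col"]], m$roi_names[idx[, "row"]],
                    sep = "__")
  v
}

#' Rebuild a connectivity matrix from its lower-triangle feature vector
#'
#' Inverse of [vectorize_connectivity()] (up to the zero diagonal).
#'
#' @param v Named vector as produced by [vectorize_connectivity()].
#' @param roi_names ROI names in atlas order.
#' @return A `connectivity_matrix`.
#' @export
devectorize_connectivity <- function(v, roi_names) {
  R <- length(roi_names)
  if (length(v) != R * (R - 1) / 2) stop("length(v) must be R(R-1)/2")
  z <- matrix(0, R, R, dimnames = list(roi_names, roi_names))
  z[lower.tri(z)] <- v
  z <- z + t(z)
  as_connectivity_matrix(z, roi_names)
}
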