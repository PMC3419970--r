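#' One-sided amplitude power spectrum of ROI time series
#'
#' Converts each ROI series to the frequency domain with the discrete Fourier
#' transform and returns the modulus `sqrt(Re^2 + Im^2)` per one-sided
#' frequency bin (bins `0 .. floor(T/2)`). No detrending or windowing is
#' applied: preprocessing is assumed to have detrended the series, and the
#' raw amplitude (not a density) is the feature. The exponent is
#' configurable: `exponent = 2` yields squared power per bin.
#'
#' @param ts T x R matrix (or vector) of ROI time series, T >= 4.
#' @param TR Repetition time in seconds (sets the frequency axis).
#' @param exponent Exponent applied to the modulus (default 1, amplitude).
#' @return An object of class `power_spectrum`: list with `amplitude`
#'   (`floor(T/2)+1` x R matrix), `freq` (Hz), and `TR`.
#' @export
power_spectrum <- function(ts, TR = 2, exponent = 1) {
  ts <- as.matrix(ts)
  nt <- nrow(ts)
  if (nt < 4) stop("need at least 4 time points")
  nb <- floor(nt / 2) + 1
  amp <- Mod(stats::mvfft(ts))[seq_len(nb), , drop = FALSE]^exponent
  freq <- (seq_len(nb) - 1) / (nt * TR)
  rownames(amp) <- sprintf("f_%04d", seq_len(nb) - 1)
  colnames(amp) <- colnames(ts)
  structure(list(amplitude = amp, freq = freq, TR = TR), class = "power_spectrum")
}

mask_indices <- function(mask) {
  which(array(as.logical(mask), dim = dim(mask)))
}

# flatten in-mask voxel series to a T x V matrix
mask_series <- function(voxels, mask) {
  d <- dim(voxels)
  stopifnot(length(d) == 4, all(d[1:3] == dim(mask)))
  idx <- mask_indices(mask)
  flat <- matrix(voxels, prod(d[1:3]), d[4])
  t(flat[idx, , drop = FALSE])
}

#' Voxelwise global connectivity map
#'
#' For every in-mask voxel, the mean Fisher-z Pearson correlation between its
#' time series and that of every *other* in-mask voxel. Constant voxels
#' cannot be correlated and contribute 0 to the averages, with a warning.
#'
#' @param voxels 4-D array (nx, ny, nz, T).
#' @param mask 3-D logical array; at least 2 in-mask voxels required.
#' @param r_max Correlation cap passed to [fisher_z()].
#' @return An object of class `voxel_map`: list with `values` (3-D array,
#'   `NA` outside the mask) and `mask`.
#' @export
global_connectivity <- function(voxels, mask, r_max = 1 - 1e-7) {
  ser <- mask_series(voxels, mask)
  V <- ncol(ser)
  if (V < 2) stop("need at least 2 in-mask voxels")
  if (nrow(ser) < 3) stop("need at least 3 time points")
  const <- apply(ser, 2, stats::sd) == 0
  if (any(const)) warning(sum(const), " constant voxel series contribute 0")
  r <- suppressWarnings(stats::cor(ser))
  r[const, ] <- 0
  r[, const] <- 0
  z <- fisher_z(r, r_max = r_max)
  diag(z) <- 0
  vals <- rowSums(z) / (V - 1)
  out <- array(NA_real_, dim = dim(mask))
  out[mask_indices(mask)] <- vals
  structure(list(values = out, mask = array(as.logical(mask), dim = dim(mask))),
            class = "voxel_map")
}

#' Kendall's coefficient of concordance (W)
#'
#' Concordance of `m` series (columns) over `n` time points (rows):
#' `W = 12 S / (m^2 (n^3 - n))`, where `S` is the sum of squared deviations
#' of the per-timepoint rank sums from their mean. Ranks are averaged over
#' ties; with `tie_correct = TRUE` the denominator subtracts the standard
#' tie term `m * sum_j T_j`, `T_j = sum (t^3 - t)` over tie groups of
#' series `j`.
#'
#' @param x n x m matrix, one series per column.
#' @param tie_correct Apply the tie correction (default `FALSE`; series are
#'   continuous so ties are measure-zero).
#' @return Kendall's W in `[0, 1]`.
#' @export
kendall_w <- function(x, tie_correct = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  if (m < 2) return(NA_real_)
  rk <- apply(x, 2, rank)
  rs <- rowSums(rk)
  S <- sum((rs - mean(rs))^2)
  denom <- m^2 * (n^3 - n)
  if (tie_correct) {
    Tj <- vapply(seq_len(m), function(j) {
      tab <- table(x[, j])
      sum(tab^3 - tab)
    }, numeric(1))
    denom <- denom - m * sum(Tj)
  }
  if (denom <= 0) return(NA_real_)
  12 * S / denom
}

#' Voxelwise regional homogeneity (ReHo) map
#'
#' For every in-mask voxel, Kendall's coefficient of concordance ([kendall_w()])
#' between its time series and those of its (up to) 26 spatially adjacent
#' in-mask neighbors. Edge-of-mask voxels use only their in-mask neighbors
#' (`m < 27`); voxels with no in-mask neighbor are undefined (`NA`).
#'
#' @param voxels 4-D array (nx, ny, nz, T), T >= 3.
#' @param mask 3-D logical array.
#' @param tie_correct Passed to [kendall_w()].
#' @return An object of class `voxel_map` with ReHo values in `[0, 1]`.
#' @export
regional_homogeneity <- function(voxels, mask, tie_correct = FALSE) {
  d <- dim(voxels)
  stopifnot(length(d) == 4)
  if (d[4] < 3) stop("need at least 3 time points")
  mask <- array(as.logical(mask), dim = d[1:3])
  flat <- matrix(voxels, prod(d[1:3]), d[4])
  out <- array(NA_real_, dim = d[1:3])
  lin <- function(x, y, z) x + d[1] * (y - 1 + d[2] * (z - 1))
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (!mask[x, y, z]) next
    xs <- max(1, x - 1):min(d[1], x + 1)
    ys <- max(1, y - 1):min(d[2], y + 1)
    zs <- max(1, z - 1):min(d[3], z + 1)
    nb <- as.vector(outer(outer(xs, ys, lin, z = 1),
                          (zs - 1) * d[1] * d[2], "+"))
    nb <- nb[mask[nb]]
    if (length(nb) < 2) next
    out[x, y, z] <- kendall_w(t(flat[nb, , drop = FALSE]),
                              tie_correct = tie_correct)
  }
  structure(list(values = out, mask = mask), class = "voxel_map")
}

#' Flatten a voxel map to a named feature vector
#'
#' @param vm A `voxel_map`.
#' @param prefix Feature-name prefix.
#' @return Named numeric vector over in-mask voxels (`<prefix>_x_y_z`).
#' @export
voxel_map_features <- function(vm, prefix = "voxel") {
  stopifnot(inherits(vm, "voxel_map"))
  idx <- which(vm$mask, arr.ind = TRUE)
  v <- vm$values[vm$mask]
  names(v) <- sprintf("%s_%d_%d_%d", prefix, idx[, 1], idx[, 2], idx[, 3])
  v
}
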