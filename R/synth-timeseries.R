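#' Generate band-limited Gaussian ROI time series
#'
#' Draws a T x R Gaussian series with a target population covariance and a
#' hard frequency pass band. Band-limiting is applied by frequency-domain
#' masking of white noise *before* covariance coloring, which makes the
#' out-of-band attenuation exact and leaves the cross-ROI covariance
#' controllable: columns are masked in the Fourier domain, re-standardized to
#' unit variance, and then colored with the Cholesky factor of `cov`.
#'
#' @param cov R x R positive-definite target covariance (correlation) matrix.
#' @param n_timepoints Number of time points T (>= 8).
#' @param TR Repetition time in seconds.
#' @param band Pass band `c(low, high)` in Hz; must satisfy
#'   `0 <= low < high <= 1/(2 TR)`. Use `c(0, 1/(2*TR))` for no filtering.
#' @param seed Integer seed.
#' @return A `n_timepoints` x R numeric matrix.
#' @export
generate_timeseries <- function(cov, n_timepoints, TR = 2,
                                band = c(0.009, 0.08), seed = 1) {
  cov <- as.matrix(cov)
  R <- ncol(cov)
  if (!isTRUE(all.equal(cov, t(cov)))) stop("cov must be symmetric")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("cov must be positive definite")
  nt <- as.integer(n_timepoints)
  if (nt < 8) stop("n_timepoints must be >= 8")
  nyq <- 1 / (2 * TR)
  if (!(band[1] >= 0 && band[1] < band[2] && band[2] <= nyq + 1e-12)) {
    stop("band must satisfy 0 <= low < high <= Nyquist")
  }
  # two-sided frequency of each DFT bin
  freq <- pmin(0:(nt - 1), nt - (0:(nt - 1))) / (nt * TR)
  keep <- freq >= band[1] & freq <= band[2]
  if (!any(keep)) stop("pass band retains no frequency bins at this T and TR")
  with_seed(seed, {
    x <- matrix(stats::rnorm(nt * R), nt, R)
    f <- stats::mvfft(x)
    f[!keep, ] <- 0
    x <- Re(stats::mvfft(f, inverse = TRUE)) / nt
    x <- scale(x)           # unit variance per column before coloring
    x <- x %*% chol(cov)
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
    x
  })
}
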