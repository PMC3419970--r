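#' Configuration for a synthetic multi-site cohort
#'
#' Defines the generative conditions for [generate_cohort()]: per-site class
#' counts, demographic distributions, the band-limited ROI time-series model
#' with class-dependent covariance on a planted edge set, a voxel-block model
#' with a class effect on regional homogeneity, and morphometric class
#' effects. The defaults reproduce the structure of the ADHD-200 training
#' release: the seven-site diagnosis table (491 TD, 163 ADHD-C, 11 ADHD-H,
#' 111 ADHD-I), a nine-point full-scale-IQ deficit in ADHD, a missing IQ
#' measure at the NI site, site-varying age ranges (no OHSU subject above 12,
#' no Pitt subject below 10), a male-skewed ADHD prevalence, and ROI series
#' band-limited to 0.009--0.08 Hz at TR = 2 s.
#'
#' @param sites Data frame with columns `site`, `n_td`, `n_adhd_c`,
#'   `n_adhd_h`, `n_adhd_i`. Defaults to the ADHD-200 training counts.
#' @param age_range_by_site Named list of `c(min, max)` ages in years.
#' @param iq_mean_by_site Named numeric vector of site mean full-scale IQ.
#' @param iq_sd Population IQ standard deviation (default 15, the full-scale
#'   IQ norm).
#' @param iq_adhd_shift Mean IQ shift for ADHD subjects (default -9 points).
#' @param iq_missing_sites Sites whose IQ is generated as missing (site-wise
#'   missingness only; default `"NI"`).
#' @param female_fraction_by_class Named vector of female fractions per
#'   diagnosis class.
#' @param n_timepoints,TR Time-series length and repetition time in seconds.
#' @param n_roi Number of ROIs.
#' @param band Pass band in Hz for the ROI series, `c(low, high)`.
#' @param base_edge_z Baseline Fisher-z connectivity on planted edges for TD
#'   subjects.
#' @param planted_edges Data frame with columns `i`, `j`, `d` (and optional
#'   `z0`): ROI pairs whose population Fisher-z connectivity differs by `d`
#'   (z-units) between ADHD and TD.
#' @param voxel_grid Integer `c(nx, ny, nz)` voxel grid, or `NULL` for no
#'   voxel data.
#' @param reho_block List with `lo` and `hi` integer coordinate triples
#'   delimiting the planted homogeneity block.
#' @param reho_base Shared-signal fraction inside the block for TD subjects.
#' @param reho_effect Additional shared-signal fraction for ADHD subjects
#'   (raises Kendall's W inside the block).
#' @param voxel_smooth Neighbor weight of the local spatial smoothing applied
#'   to the voxel noise.
#' @param morph_effect Data frame with columns `column`, `d`: morphometric
#'   features given a standardized class difference `d`.
#' @param seed Integer master seed; all generated data are a deterministic
#'   function of the configuration and this seed.
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(sites = adhd200_site_counts(),
                          age_range_by_site = NULL,
                          iq_mean_by_site = NULL,
                          iq_sd = 15,
                          iq_adhd_shift = -9,
                          iq_missing_sites = "NI",
                          female_fraction_by_class = c("TD" = 0.47, "ADHD-C" = 0.18,
                                                       "ADHD-H" = 0.20, "ADHD-I" = 0.26),
                          n_timepoints = 176,
                          TR = 2,
                          n_roi = 90,
                          band = c(0.009, 0.08),
                          base_edge_z = 0.2,
                          planted_edges = NULL,
                          voxel_grid = NULL,
                          reho_block = NULL,
                          reho_base = 0.2,
                          reho_effect = 0,
                          voxel_smooth = 0.3,
                          morph_effect = NULL,
                          seed = 1) {
  sites <- as.data.frame(sites)
  need <- c("site", "n_td", "n_adhd_c", "n_adhd_h", "n_adhd_i")
  if (!all(need %in% names(sites))) {
    stop("`sites` must have columns ", paste(need, collapse = ", "))
  }
  counts <- as.matrix(sites[, need[-1]])
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("site class counts must be non-negative integers")
  }
  if (!is.numeric(n_timepoints) || n_timepoints < 8) stop("n_timepoints must be >= 8")
  if (!is.numeric(n_roi) || n_roi < 2) stop("n_roi must be >= 2")
  if (TR <= 0) stop("TR must be positive")
  nyq <- 1 / (2 * TR)
  if (!(length(band) == 2 && band[1] >= 0 && band[1] < band[2] && band[2] <= nyq)) {
    stop("band must satisfy 0 <= low < high <= Nyquist (", format(nyq), " Hz)")
  }
  if (!is.null(planted_edges)) {
    planted_edges <- as.data.frame(planted_edges)
    stopifnot(all(c("i", "j", "d") %in% names(planted_edges)))
    if (any(!is.finite(planted_edges$d))) stop("planted edge effect sizes must be finite")
    if (any(planted_edges$i == planted_edges$j) ||
        any(planted_edges$i > n_roi) || any(planted_edges$j > n_roi) ||
        any(planted_edges$i < 1) || any(planted_edges$j < 1)) {
      stop("planted edges must index distinct ROIs in 1..n_roi")
    }
  }
  if (!is.null(morph_effect)) {
    morph_effect <- as.data.frame(morph_effect)
    stopifnot(all(c("column", "d") %in% names(morph_effect)))
    if (any(!is.finite(morph_effect$d))) stop("morphometric effect sizes must be finite")
    bad <- setdiff(morph_effect$column, morphometry_feature_names())
    if (length(bad)) stop("unknown morphometry column(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(voxel_grid)) {
    stopifnot(length(voxel_grid) == 3, all(voxel_grid >= 1))
    if (is.null(reho_block)) {
      reho_block <- list(lo = pmin(voxel_grid, c(2, 2, 2)), hi = pmin(voxel_grid, c(4, 4, 4)))
    }
    if (reho_base < 0 || reho_base + max(reho_effect, 0) >= 1) {
      stop("shared-signal fractions must lie in [0, 1)")
    }
  }
  if (any(female_fraction_by_class < 0) || any(female_fraction_by_class > 1)) {
    stop("female fractions must lie in [0, 1]")
  }
  if (is.null(age_range_by_site)) {
    defaults <- list(Peking = c(8, 17), KKI = c(8, 13), NI = c(11, 22),
                     NYU = c(7, 18), OHSU = c(7, 12), Pitt = c(10, 20),
                     WashU = c(7, 21))
    age_range_by_site <- lapply(sites$site, function(s) defaults[[s]] %||% c(7, 18))
    names(age_range_by_site) <- sites$site
  }
  if (is.null(iq_mean_by_site)) {
    defaults <- c(Peking = 110, KKI = 110, NI = 105, NYU = 108, OHSU = 115,
                  Pitt = 110, WashU = 112)
    iq_mean_by_site <- vapply(sites$site, function(s) {
      if (s %in% names(defaults)) defaults[[s]] else 108
    }, numeric(1))
    names(iq_mean_by_site) <- sites$site
  }
  structure(list(
    sites = sites, age_range_by_site = age_range_by_site,
    iq_mean_by_site = iq_mean_by_site, iq_sd = iq_sd,
    iq_adhd_shift = iq_adhd_shift, iq_missing_sites = iq_missing_sites,
    female_fraction_by_class = female_fraction_by_class,
    n_timepoints = as.integer(n_timepoints), TR = TR, n_roi = as.integer(n_roi),
    band = band, base_edge_z = base_edge_z, planted_edges = planted_edges,
    voxel_grid = voxel_grid, reho_block = reho_block, reho_base = reho_base,
    reho_effect = reho_effect, voxel_smooth = voxel_smooth,
    morph_effect = morph_effect, seed = as.integer(seed)
  ), class = "cohort_config")
}

roi_names <- function(n_roi) sprintf("roi_%03d", seq_len(n_roi))

# class covariance: identity plus planted Fisher-z edges (z0 for TD, z0 + d
# for ADHD); positive definiteness is a configuration requirement
class_covariances <- function(config) {
  R <- config$n_roi
  make_cov <- function(adhd) {
    S <- diag(R)
    pe <- config$planted_edges
    if (!is.null(pe)) {
      z0 <- if ("z0" %in% names(pe)) pe$z0 else rep(config$base_edge_z, nrow(pe))
      for (k in seq_len(nrow(pe))) {
        z <- z0[k] + if (adhd) pe$d[k] else 0
        S[pe$i[k], pe$j[k]] <- S[pe$j[k], pe$i[k]] <- tanh(z)
      }
    }
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
      stop("planted-edge covariance is not positive definite; reduce effect sizes")
    }
    S
  }
  list(TD = make_cov(FALSE), ADHD = make_cov(TRUE))
}

#' Generate a synthetic multi-site cohort
#'
#' Draws a full cohort under a [cohort_config()]: a phenotype table with
#' exact per-site/class/gender counts, per-subject band-limited ROI time
#' series whose population covariance differs between classes on the planted
#' edge set, optional voxel-block time series with a class effect on regional
#' homogeneity, and a morphometry table with planted standardized class
#' differences. Output is a deterministic function of the configuration and
#' its seed.
#'
#' @param config A [cohort_config()].
#' @return A list of class `adhd_cohort` with elements `phenotypes` (data
#'   frame), `timeseries` (named list of T x R matrices), `voxels` (named
#'   list of 4-D arrays, or `NULL`), `voxel_mask` (logical 3-D array, or
#'   `NULL`), `morphometry` (data frame), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  pheno <- with_seed(derive_seed(config$seed, "phenotypes"),
                     generate_phenotypes(config))
  covs <- class_covariances(config)
  ts <- lapply(seq_len(nrow(pheno)), function(i) {
    cls <- if (pheno$dx[i] == "TD") "TD" else "ADHD"
    x <- generate_timeseries(covs[[cls]], config$n_timepoints, config$TR,
                             band = config$band,
                             seed = derive_seed(config$seed, paste0("ts/", pheno$subject_id[i])))
    colnames(x) <- roi_names(config$n_roi)
    x
  })
  names(ts) <- pheno$subject_id
  vox <- NULL
  mask <- NULL
  if (!is.null(config$voxel_grid)) {
    mask <- array(TRUE, dim = config$voxel_grid)
    vox <- lapply(seq_len(nrow(pheno)), function(i) {
      a <- config$reho_base + if (pheno$dx[i] == "TD") 0 else config$reho_effect
      generate_voxel_block(config$voxel_grid, config$n_timepoints,
                           block = config$reho_block, shared_fraction = a,
                           smooth = config$voxel_smooth,
                           seed = derive_seed(config$seed, paste0("vox/", pheno$subject_id[i])))
    })
    names(vox) <- pheno$subject_id
  }
  morph <- with_seed(derive_seed(config$seed, "morphometry"),
                     generate_morphometry_table(pheno, config))
  structure(list(phenotypes = pheno, timeseries = ts, voxels = vox,
                 voxel_mask = mask, morphometry = morph, config = config),
            class = "adhd_cohort")
}

generate_phenotypes <- function(config) {
  rows <- list()
  classes <- dx_levels()
  count_cols <- c("n_td", "n_adhd_c", "n_adhd_h", "n_adhd_i")
  for (s in seq_len(nrow(config$sites))) {
    site <- config$sites$site[s]
    rng <- config$age_range_by_site[[site]]
    iq_mu <- config$iq_mean_by_site[[site]]
    for (k in seq_along(classes)) {
      n <- config$sites[[count_cols[k]]][s]
      if (n == 0) next
      dx <- classes[k]
      n_f <- round(config$female_fraction_by_class[[dx]] * n)
      gender <- c(rep("F", n_f), rep("M", n - n_f))
      age <- stats::runif(n, rng[1], rng[2])
      iq <- stats::rnorm(n, iq_mu + if (dx == "TD") 0 else config$iq_adhd_shift,
                         config$iq_sd)
      if (site %in% config$iq_missing_sites) iq <- rep(NA_real_, n)
      handed <- ifelse(stats::runif(n) < 0.9, "R", "L")
      rows[[length(rows) + 1]] <- data.frame(
        site = site, dx = dx, age = age, gender = gender, iq = iq,
        handedness = handed, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$subject_id <- sprintf("%s_%04d", out$site, stats::ave(seq_len(nrow(out)),
                                                           out$site, FUN = seq_along))
  out$dx <- factor(out$dx, levels = classes)
  out[, c("subject_id", "site", "dx", "age", "gender", "iq", "handedness")]
}

# voxel-block generator: locally smoothed Gaussian noise per voxel, plus a
# shared block signal whose variance fraction carries the class effect on
# regional homogeneity
generate_voxel_block <- function(grid, n_timepoints, block, shared_fraction,
                                 smooth = 0.3, seed = 1) {
  stopifnot(shared_fraction >= 0, shared_fraction < 1)
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]; nt <- n_timepoints
  with_seed(seed, {
    arr <- array(stats::rnorm(nx * ny * nz * nt), dim = c(nx, ny, nz, nt))
    if (smooth > 0) {
      sm <- arr
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        xs <- intersect(seq_len(nx), seq_len(nx) - dx)
        ys <- intersect(seq_len(ny), seq_len(ny) - dy)
        zs <- intersect(seq_len(nz), seq_len(nz) - dz)
        sm[xs, ys, zs, ] <- sm[xs, ys, zs, , drop = FALSE] +
          smooth * arr[xs + dx, ys + dy, zs + dz, , drop = FALSE]
      }
      arr <- sm
    }
    # per-voxel standardization so the shared fraction is an exact variance share
    dim(arr) <- c(nx * ny * nz, nt)
    arr <- (arr - rowMeans(arr)) / apply(arr, 1, stats::sd)
    if (shared_fraction > 0 && !is.null(block)) {
      g <- stats::rnorm(nt)
      g <- (g - mean(g)) / stats::sd(g)
      vol_idx <- array(seq_len(nx * ny * nz), dim = c(nx, ny, nz))
      sel <- as.vector(vol_idx[block$lo[1]:block$hi[1],
                               block$lo[2]:block$hi[2],
                               block$lo[3]:block$hi[3]])
      arr[sel, ] <- sqrt(1 - shared_fraction) * arr[sel, , drop = FALSE] +
        sqrt(shared_fraction) * matrix(g, length(sel), nt, byrow = TRUE)
    }
    dim(arr) <- c(nx, ny, nz, nt)
    arr
  })
}
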