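# Synthetic multi-site cohort generator

test_that("phenotype counts exactly match the configuration", {
  cfg <- cohort_config(sites = data.frame(site = "NI", n_td = 23, n_adhd_c = 18,
                                          n_adhd_h = 6, n_adhd_i = 1),
                       n_timepoints = 16, n_roi = 3, seed = 4)
  ph <- generate_morphometry(cfg)[, c("subject_id", "site", "dx")]
  expect_equal(as.vector(table(ph$dx)), c(23, 18, 6, 1))

  cfg2 <- cohort_config(sites = small_site_counts(), n_timepoints = 16,
                        n_roi = 3, seed = 9)
  co <- generate_cohort(cfg2)
  tab <- table(co$phenotypes$site, co$phenotypes$dx)
  expect_equal(as.vector(tab["SiteA", ]), c(12, 6, 0, 2))
  expect_equal(as.vector(tab["SiteB", ]), c(10, 4, 0, 4))
  expect_false(any(duplicated(co$phenotypes$subject_id)))
  # gender counts are exact: round(frac * n) females per site/class cell
  fr <- cfg2$female_fraction_by_class
  n_f <- sum(co$phenotypes$gender[co$phenotypes$site == "SiteA" &
                                    co$phenotypes$dx == "TD"] == "F")
  expect_equal(n_f, round(fr[["TD"]] * 12))
})

test_that("identical config and seed give bit-identical cohorts", {
  cfg <- cohort_config(sites = small_site_counts(), n_timepoints = 24,
                       n_roi = 4, voxel_grid = c(3, 3, 3), seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(a$voxels, b$voxels)
  expect_identical(a$morphometry, b$morphometry)
})

test_that("ADHD mean IQ is shifted by the configured amount", {
  # expected sample shift: -9 +/- 2 * SE, SE = iq_sd * sqrt(2 / n)
  n <- 200
  cfg <- cohort_config(sites = data.frame(site = "S", n_td = n, n_adhd_c = n,
                                          n_adhd_h = 0, n_adhd_i = 0),
                       iq_missing_sites = character(0),
                       n_timepoints = 16, n_roi = 3, seed = 5)
  ph2 <- generate_cohort(cfg)$phenotypes
  diff <- mean(ph2$iq[ph2$dx != "TD"]) - mean(ph2$iq[ph2$dx == "TD"])
  se <- 15 * sqrt(2 / n)
  expect_lt(abs(diff - (-9)), 2 * se)
})

test_that("missing-IQ sites carry an explicit missing marker, not zero", {
  cfg <- cohort_config(sites = small_site_counts(sites = c("NI", "Other")),
                       iq_missing_sites = "NI", n_timepoints = 16, n_roi = 3)
  ph <- generate_cohort(cfg)$phenotypes
  expect_true(all(is.na(ph$iq[ph$site == "NI"])))
  expect_true(all(!is.na(ph$iq[ph$site == "Other"])))
})

test_that("configuration validation rejects invalid inputs", {
  expect_error(cohort_config(sites = data.frame(site = "A", n_td = -1,
                                                n_adhd_c = 0, n_adhd_h = 0,
                                                n_adhd_i = 0)),
               "non-negative")
  expect_error(cohort_config(sites = small_site_counts(), n_timepoints = 4),
               ">= 8")
  expect_error(cohort_config(sites = small_site_counts(), n_roi = 1), ">= 2")
  expect_error(cohort_config(sites = small_site_counts(),
                             planted_edges = data.frame(i = 1, j = 2, d = Inf)),
               "finite")
  expect_error(cohort_config(sites = small_site_counts(), TR = 2,
                             band = c(0.1, 0.5)), "Nyquist")
})

test_that("generated series reproduce the target covariance structure", {
  # independence: identity covariance leaves off-diagonal correlations small
  x <- generate_timeseries(diag(5), 10000, TR = 2, band = c(0.01, 0.2), seed = 3)
  r <- cor(x)
  expect_lt(mean(abs(r[upper.tri(r)])), 0.05)

  # a planted r = 0.6 pair is recovered within sampling error
  S <- diag(3); S[1, 2] <- S[2, 1] <- 0.6
  x <- generate_timeseries(S, 5000, TR = 2, band = c(0.01, 0.2), seed = 8)
  expect_lt(abs(cor(x[, 1], x[, 2]) - 0.6), 0.05)

  expect_error(generate_timeseries(matrix(c(1, 2, 2, 1), 2), 100),
               "positive definite")
})

test_that("band-limiting attenuates out-of-band power", {
  TR <- 2
  x <- generate_timeseries(diag(3), 2048, TR = TR, band = c(0.009, 0.08),
                           seed = 2)
  ps <- power_spectrum(x, TR = TR)
  inband <- ps$freq >= 0.009 & ps$freq <= 0.08
  ratio <- sum(ps$amplitude[!inband, ]^2) / sum(ps$amplitude[inband, ]^2)
  expect_lt(ratio, 0.1)
})

test_that("morphometry has the full 747-column battery", {
  expect_length(morphometry_feature_names(), 9 * 34 * 2 + 3 * 45)
  cfg <- cohort_config(sites = small_site_counts(), n_timepoints = 16, n_roi = 3)
  morph <- generate_morphometry(cfg)
  expect_equal(sum(colnames(morph) %in% morphometry_feature_names()), 747)
})

test_that("planted morphometric effects have the configured size and none leak", {
  n <- 100
  target <- "lh_posteriorcingulate_ThickStd"
  cfg <- cohort_config(sites = data.frame(site = "S", n_td = n, n_adhd_c = n,
                                          n_adhd_h = 0, n_adhd_i = 0),
                       morph_effect = data.frame(column = target, d = 1),
                       n_timepoints = 16, n_roi = 3, seed = 31)
  morph <- generate_morphometry(cfg)
  adhd <- morph$dx != "TD"
  pooled_sd <- function(v) sqrt((var(v[adhd]) + var(v[!adhd])) / 2)
  dhat <- (mean(morph[[target]][adhd]) - mean(morph[[target]][!adhd])) /
    pooled_sd(morph[[target]])
  expect_lt(abs(dhat - 1), 0.3)
  # an untouched column shows no systematic class difference
  other <- "rh_precuneus_ThickAvg"
  dnull <- (mean(morph[[other]][adhd]) - mean(morph[[other]][!adhd])) /
    pooled_sd(morph[[other]])
  expect_lt(abs(dnull), 0.3)
})

test_that("planted edges separate the classes in population covariance", {
  cfg <- cohort_config(sites = small_site_counts(), n_roi = 6,
                       planted_edges = data.frame(i = 1, j = 2, d = 1),
                       n_timepoints = 3000, TR = 2, band = c(0.01, 0.2),
                       seed = 12)
  co <- generate_cohort(cfg)
  ph <- co$phenotypes
  z12 <- vapply(ph$subject_id, function(id) {
    atanh(cor(co$timeseries[[id]][, 1], co$timeseries[[id]][, 2]))
  }, numeric(1))
  gap <- mean(z12[ph$dx != "TD"]) - mean(z12[ph$dx == "TD"])
  expect_lt(abs(gap - 1), 0.25)
})
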