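# Functional features: Fisher-z connectivity, spectra, voxelwise maps

test_that("fisher_z is the capped atanh", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  expect_error(fisher_z(1.2), "<= 1")
})

test_that("connectivity matrix matches the direct covariance-formula oracle", {
  set.seed(10)
  ts <- matrix(rnorm(100), 20, 5)
  m <- connectivity_matrix(ts)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(m$z[i, j], atanh(oracle_pearson(ts[, i], ts[, j])),
                 tolerance = 1e-10)
  }
  expect_equal(m$z, t(m$z))
  expect_equal(diag(m$z), setNames(rep(0, 5), m$roi_names))
})

test_that("connectivity handles perfect correlation, orthogonality, degeneracy", {
  t_axis <- seq_len(32)
  a <- sin(2 * pi * t_axis / 8)
  b <- cos(2 * pi * t_axis / 8)   # orthogonal, zero-mean
  m <- connectivity_matrix(cbind(x = a, y = a, z = b))
  expect_equal(m$z["x", "y"], atanh(1 - 1e-7))
  expect_equal(m$z["x", "z"], 0, tolerance = 1e-10)

  expect_warning(mc <- connectivity_matrix(cbind(a = a, b = b, c = rep(1, 32))),
                 "constant")
  expect_equal(mc$z["c", "a"], 0)
  expect_error(connectivity_matrix(matrix(1:4, 2, 2)), "3 time points")
})

test_that("connectivity is invariant to affine rescaling of each column", {
  set.seed(3)
  ts <- matrix(rnorm(90), 30, 3)
  ts2 <- sweep(sweep(ts, 2, c(2, -5, 0.1), "*"), 2, c(10, -3, 7), "+")
  expect_equal(abs(connectivity_matrix(ts)$z), abs(connectivity_matrix(ts2)$z),
               tolerance = 1e-10)
})

test_that("lower-triangle vectorization has canonical size and names", {
  R <- 111
  z <- matrix(0, R, R)
  m <- as_connectivity_matrix(z)
  expect_length(vectorize_connectivity(m), R * (R - 1) / 2)  # 6105

  m2 <- as_connectivity_matrix(matrix(c(0, 0.3, 0.3, 0), 2),
                               roi_names = c("a", "b"))
  v2 <- vectorize_connectivity(m2)
  expect_equal(v2, c(a__b = 0.3))

  set.seed(4)
  m3 <- connectivity_matrix(matrix(rnorm(60), 12, 5))
  v3 <- vectorize_connectivity(m3)
  expect_equal(devectorize_connectivity(v3, m3$roi_names)$z, m3$z)
})

test_that("power spectrum obeys DC, single-tone and Parseval identities", {
  ps <- power_spectrum(matrix(3, 8, 1), TR = 2)
  expect_equal(unname(ps$amplitude[1, 1]), 8 * 3)
  expect_equal(unname(ps$amplitude[-1, 1]), rep(0, 4), tolerance = 1e-10)

  nt <- 32; k <- 5
  tone <- sin(2 * pi * k * (0:(nt - 1)) / nt)
  psk <- power_spectrum(tone, TR = 2)
  peaks <- which(psk$amplitude[, 1] > 1e-8)
  expect_equal(unname(peaks), k + 1)

  set.seed(5)
  x <- rnorm(30)
  amp <- power_spectrum(x, TR = 1)$amplitude[, 1]
  two_sided <- unname(amp[1]^2 + 2 * sum(amp[2:15]^2) + amp[16]^2)
  expect_equal(two_sided, length(x) * sum(x^2), tolerance = 1e-8)

  # frequency axis from T and TR
  expect_equal(power_spectrum(x, TR = 2)$freq[2], 1 / (30 * 2))
  expect_equal(power_spectrum(x, TR = 2, exponent = 2)$amplitude,
               power_spectrum(x, TR = 2)$amplitude^2)
})

test_that("global connectivity equals the explicit double-loop oracle", {
  set.seed(6)
  dims <- c(3, 2, 2)
  arr <- array(rnorm(prod(dims) * 40), dim = c(dims, 40))
  mask <- array(TRUE, dim = dims)
  gm <- global_connectivity(arr, mask)
  ser <- t(matrix(arr, prod(dims), 40))
  expect_equal(gm$values[mask], oracle_gcor(ser), tolerance = 1e-10)
})

test_that("global connectivity limiting cases behave", {
  nt <- 20
  shared <- rnorm(nt)
  arr <- array(rep(shared, each = 4), dim = c(2, 2, 1, nt))
  # every voxel carries the same series -> capped perfect correlation
  arr <- aperm(array(shared, dim = c(nt, 2, 2, 1)), c(2, 3, 4, 1))
  mask <- array(TRUE, dim = c(2, 2, 1))
  gm <- global_connectivity(arr, mask)
  expect_equal(unname(gm$values[mask]), rep(atanh(1 - 1e-7), 4))

  # an independent voxel converges to zero mean z at large T
  set.seed(7)
  nt <- 4000
  arr2 <- array(rnorm(8 * nt), dim = c(2, 2, 2, nt))
  g2 <- global_connectivity(arr2, array(TRUE, dim = c(2, 2, 2)))
  expect_lt(max(abs(g2$values)), 0.05)
})

test_that("Kendall's W matches exhaustive rank-sum computation", {
  # perfect concordance
  base <- seq_len(10)
  X <- sapply(1:27, function(j) base * j)
  expect_equal(kendall_w(X), 1)

  # m = 3, n = 3 toy: oracle by explicit enumeration
  toy <- cbind(c(1, 2, 3), c(2, 1, 3), c(1, 3, 2))
  expect_equal(kendall_w(toy), oracle_kendall_w(toy))
  # hand computation: rank sums (4, 6, 8), S = 8, W = 12*8/(9*24)
  expect_equal(kendall_w(toy), 12 * 8 / (9 * (27 - 3)))

  set.seed(8)
  for (rep in 1:5) {
    X <- matrix(rnorm(12 * 5), 12, 5)
    expect_equal(kendall_w(X), oracle_kendall_w(X), tolerance = 1e-12)
  }
})

test_that("independent series have concordance near the 1/m null", {
  set.seed(9)
  m <- 5
  w <- replicate(300, kendall_w(matrix(rnorm(20 * m), 20, m)))
  expect_lt(abs(mean(w) - 1 / m), 0.02)
})

test_that("ReHo maps are rank-invariant and handle mask edges", {
  set.seed(11)
  dims <- c(4, 4, 3)
  arr <- array(rnorm(prod(dims) * 15), dim = c(dims, 15))
  mask <- array(TRUE, dim = dims)
  rh <- regional_homogeneity(arr, mask)
  expect_true(all(rh$values[mask] >= 0 & rh$values[mask] <= 1))

  # monotone transformation of every series leaves W unchanged
  rh2 <- regional_homogeneity(exp(arr), mask)
  expect_equal(rh$values, rh2$values, tolerance = 1e-12)

  # identical series in a full 27-neighborhood give W = 1
  shared <- rnorm(15)
  arr3 <- array(rep(shared, each = 27), dim = c(3, 3, 3, 15))
  rh3 <- regional_homogeneity(arr3, array(TRUE, dim = c(3, 3, 3)))
  expect_equal(rh3$values[2, 2, 2], 1)

  # a voxel with no in-mask neighbor is undefined
  m2 <- array(FALSE, dim = dims); m2[1, 1, 1] <- TRUE; m2[4, 4, 3] <- TRUE
  rh4 <- regional_homogeneity(arr, m2)
  expect_true(is.na(rh4$values[1, 1, 1]))
})

test_that("ReHo agrees with the brute-force W oracle on a small grid", {
  set.seed(12)
  dims <- c(5, 5, 5)
  arr <- array(rnorm(prod(dims) * 12), dim = c(dims, 12))
  mask <- array(TRUE, dim = dims)
  rh <- regional_homogeneity(arr, mask)
  flat <- matrix(arr, prod(dims), 12)
  for (v in list(c(1, 1, 1), c(3, 3, 3), c(5, 2, 4), c(2, 5, 1))) {
    xs <- max(1, v[1] - 1):min(dims[1], v[1] + 1)
    ys <- max(1, v[2] - 1):min(dims[2], v[2] + 1)
    zs <- max(1, v[3] - 1):min(dims[3], v[3] + 1)
    nb <- as.vector(outer(outer(xs, (ys - 1) * dims[1], "+"),
                          (zs - 1) * dims[1] * dims[2], "+"))
    expect_equal(rh$values[v[1], v[2], v[3]],
                 oracle_kendall_w(t(flat[nb, ])), tolerance = 1e-12)
  }
})
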