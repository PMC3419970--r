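# Brain graphs: proportional thresholding and network metrics

test_that("proportional thresholding keeps the right edge count", {
  set.seed(20)
  z <- matrix(rnorm(100), 10, 10); z <- (z + t(z)) / 2; diag(z) <- 0
  m <- as_connectivity_matrix(z)
  g <- threshold_proportional(m, 0.2)
  expect_equal(sum(g$adj > 0) / 2, round(0.2 * 45))  # 9 edges

  # retained set equals a sort-based oracle when all weights are distinct
  w <- z[upper.tri(z)]
  cutoff <- sort(w[w > 0], decreasing = TRUE)[9]
  kept <- g$adj[upper.tri(g$adj)]
  expect_setequal(kept[kept > 0], w[w > 0 & w >= cutoff])

  # p = 1 keeps all positives (with a shortfall warning), drops all negatives
  expect_warning(threshold_proportional(m, 1), "positive")
  expect_equal(sum(suppressWarnings(threshold_proportional(m, 1)$adj > 0)) / 2,
               sum(w > 0))
  expect_true(all(suppressWarnings(threshold_proportional(m, 1)$adj) >= 0))

  expect_error(threshold_proportional(m, 0), "sparsity")
  bg <- threshold_proportional(m, 0.2, mode = "binarized")
  expect_true(all(bg$adj %in% c(0, 1)))
})

test_that("global metrics match closed forms on canonical graphs", {
  K4 <- as_brain_graph(matrix(1, 4, 4) - diag(4), mode = "binarized")
  gm <- global_graph_metrics(K4)
  expect_equal(gm$cc, 1)
  expect_equal(gm$cpl, 1)
  expect_equal(gm$eglob, 1)

  ring <- matrix(0, 6, 6)
  for (i in 1:6) { j <- i %% 6 + 1; ring[i, j] <- ring[j, i] <- 1 }
  gr <- global_graph_metrics(as_brain_graph(ring, mode = "binarized"))
  expect_equal(gr$cpl, 1.8)   # mean of distances 1,2,3 over 15 pairs
  expect_equal(gr$cc, 0)

  empty <- as_brain_graph(matrix(0, 4, 4), mode = "binarized")
  ge <- global_graph_metrics(empty)
  expect_equal(ge$cc, 0)
  expect_equal(ge$eglob, 0)
  expect_true(is.infinite(ge$cpl))
  expect_true(ge$disconnected)
})

test_that("nodal metrics match path enumeration on a star and K4", {
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  nm <- nodal_graph_metrics(as_brain_graph(star, mode = "binarized"))
  expect_equal(nm$bc, c(1, 0, 0, 0, 0))   # all 6 leaf pairs route via center
  expect_equal(nm$strength, c(4, 1, 1, 1, 1))

  K4 <- as_brain_graph(matrix(1, 4, 4) - diag(4), mode = "binarized")
  expect_equal(nodal_graph_metrics(K4)$ereg, rep(1, 4))

  iso <- matrix(0, 4, 4); iso[1, 2] <- iso[2, 1] <- 1; iso[2, 3] <- iso[3, 2] <- 1
  nmi <- nodal_graph_metrics(as_brain_graph(iso, mode = "binarized"))
  expect_equal(unlist(nmi[4, c("strength", "degree", "cc", "eloc", "ereg", "bc")]),
               c(strength = 0, degree = 0, cc = 0, eloc = 0, ereg = 0, bc = 0))
})

test_that("all metrics equal brute-force oracles on random small graphs", {
  set.seed(77)
  for (rep in 1:60) {
    R <- sample(4:8, 1)
    weighted <- rep %% 2 == 0
    adj <- random_adjacency(R, density = runif(1, 0.3, 0.9), weighted = weighted)
    g <- as_brain_graph(adj, mode = if (weighted) "weighted" else "binarized")
    gm <- global_graph_metrics(g)
    nm <- nodal_graph_metrics(g)
    expect_equal(gm$cpl, oracle_cpl(g$adj, weighted), tolerance = 1e-10)
    expect_equal(gm$eglob, oracle_eglob(g$adj, weighted), tolerance = 1e-10)
    expect_equal(unname(gm$cc), mean(oracle_clustering(g$adj, weighted)),
                 tolerance = 1e-10)
    expect_equal(gm$eloc, mean(oracle_eloc(g$adj, weighted)), tolerance = 1e-10)
    expect_equal(nm$ereg, oracle_ereg(g$adj, weighted), tolerance = 1e-10)
    expect_equal(nm$cc, unname(oracle_clustering(g$adj, weighted)),
                 tolerance = 1e-10)
    expect_equal(nm$bc, oracle_betweenness(g$adj, weighted), tolerance = 1e-10)
  }
})

test_that("modularity of the returned partition is consistent and non-negative", {
  set.seed(30)
  # two dense blocks, sparse bridge
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  A[4, 5] <- A[5, 4] <- 1
  g <- as_brain_graph(A, mode = "binarized")
  gm <- global_graph_metrics(g)
  expect_gte(gm$q, 0)  # at least as good as the one-community partition
  ig <- igraph::graph_from_adjacency_matrix(g$adj, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  cm <- with_seed(1, igraph::cluster_louvain(ig, weights = igraph::E(ig)$weight))
  expect_equal(oracle_modularity(A, igraph::membership(cm)),
               max(cm$modularity), tolerance = 1e-10)
})

test_that("metric values are invariant to node relabeling", {
  set.seed(31)
  adj <- random_adjacency(7, density = 0.5, weighted = TRUE)
  perm <- sample(7)
  g1 <- global_graph_metrics(as_brain_graph(adj, mode = "weighted"))
  g2 <- global_graph_metrics(as_brain_graph(adj[perm, perm], mode = "weighted"))
  for (f in c("cc", "eloc", "cpl", "eglob")) expect_equal(g1[[f]], g2[[f]])
  n1 <- nodal_graph_metrics(as_brain_graph(adj, mode = "weighted"))
  n2 <- nodal_graph_metrics(as_brain_graph(adj[perm, perm], mode = "weighted"))
  expect_equal(n1$bc[perm], n2$bc, tolerance = 1e-10)
  expect_equal(n1$strength[perm], n2$strength, tolerance = 1e-10)
})

test_that("random-network normalization is self-consistent and seeded", {
  set.seed(32)
  er <- (random_adjacency(24, density = 0.3, weighted = FALSE) > 0) * 1
  g <- as_brain_graph(er, mode = "binarized")
  nz <- normalized_metrics(g, n_random = 40, seed = 5)
  # a graph drawn from the null family sits within 3 ensemble SD of 1
  expect_lt(abs(nz$gamma - 1), 3 * nz$cc_rand_sd / nz$cc_rand + 1e-9)
  expect_lt(abs(nz$lambda - 1), 3 * nz$cpl_rand_sd / nz$cpl_rand + 1e-9)
  expect_equal(nz$sigma, nz$gamma / nz$lambda)
  expect_identical(normalized_metrics(g, n_random = 10, seed = 5)$gamma,
                   normalized_metrics(g, n_random = 10, seed = 5)$gamma)

  # ring lattice: clustered relative to rewired nulls
  n <- 20
  lat <- matrix(0, n, n)
  for (i in 1:n) for (s in 1:2) {
    j <- (i + s - 1) %% n + 1
    lat[i, j] <- lat[j, i] <- 1
  }
  nz2 <- normalized_metrics(as_brain_graph(lat, mode = "binarized"),
                            n_random = 30, seed = 6)
  expect_gt(nz2$gamma, 1)
})

test_that("sparsity averaging equals the mean of per-level metrics", {
  set.seed(33)
  z <- matrix(rnorm(144, mean = 0.3), 12, 12); z <- (z + t(z)) / 2; diag(z) <- 0
  m <- as_connectivity_matrix(z)
  levels <- c(0.2, 0.3)
  avg <- metrics_across_sparsities(m, levels = levels, mode = "binarized",
                                   n_random = 0, seed = 2)
  per <- sapply(levels, function(p) {
    g <- threshold_proportional(m, p, mode = "binarized")
    global_graph_metrics(g, seed = derive_seed(2, paste0("q", which(levels == p))))$eglob
  })
  expect_equal(unname(avg["global_eglob"]), mean(per), tolerance = 1e-12)
  # binarized global efficiency is non-decreasing as edges are added
  effs <- sapply(c(0.1, 0.2, 0.4, 0.8), function(p) {
    g <- suppressWarnings(threshold_proportional(m, p, mode = "binarized"))
    global_graph_metrics(g)$eglob
  })
  expect_true(all(diff(effs) >= -1e-12))
})
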