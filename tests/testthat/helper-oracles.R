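# Independent brute-force oracles used to validate the package's
# implementations on small instances. These deliberately avoid the code
# paths (and where possible the library calls) they are checking.

# Pearson correlation straight from the covariance formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# average ranks by pairwise counting (no call to rank())
oracle_ranks <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    less <- sum(x < x[i])
    ties <- sum(x == x[i])
    less + (ties + 1) / 2
  }, numeric(1))
}

# Kendall's W by explicit rank-sum computation
oracle_kendall_w <- function(X) {
  n <- nrow(X)
  m <- ncol(X)
  R <- sapply(seq_len(m), function(j) oracle_ranks(X[, j]))
  rs <- rowSums(R)
  S <- sum((rs - mean(rs))^2)
  12 * S / (m^2 * (n^3 - n))
}

# per-voxel mean Fisher-z correlation by an explicit double loop
oracle_gcor <- function(series) {   # series: T x V
  V <- ncol(series)
  vapply(seq_len(V), function(v) {
    tot <- 0
    for (u in seq_len(V)) {
      if (u == v) next
      r <- oracle_pearson(series[, v], series[, u])
      r <- max(min(r, 1 - 1e-7), -(1 - 1e-7))
      tot <- tot + atanh(r)
    }
    tot / (V - 1)
  }, numeric(1))
}

# all-pairs shortest path distances by Floyd-Warshall (lengths 1/w for
# weighted adjacency, 1 for binary)
oracle_distances <- function(adj, weighted) {
  R <- ncol(adj)
  D <- matrix(Inf, R, R)
  diag(D) <- 0
  for (i in seq_len(R)) for (j in seq_len(R)) {
    if (i != j && adj[i, j] > 0) D[i, j] <- if (weighted) 1 / adj[i, j] else 1
  }
  for (k in seq_len(R)) for (i in seq_len(R)) for (j in seq_len(R)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

oracle_cpl <- function(adj, weighted) {
  D <- oracle_distances(adj, weighted)
  off <- D[upper.tri(D)]
  off <- off[is.finite(off)]
  if (length(off)) mean(off) else Inf
}

oracle_eglob <- function(adj, weighted) {
  D <- oracle_distances(adj, weighted)
  R <- ncol(D)
  tot <- 0
  for (i in seq_len(R)) for (j in seq_len(R)) {
    if (i != j && is.finite(D[i, j])) tot <- tot + 1 / D[i, j]
  }
  tot / (R * (R - 1))
}

oracle_ereg <- function(adj, weighted) {
  D <- oracle_distances(adj, weighted)
  R <- ncol(D)
  vapply(seq_len(R), function(i) {
    s <- 0
    for (j in seq_len(R)) if (j != i && is.finite(D[i, j])) s <- s + 1 / D[i, j]
    s / (R - 1)
  }, numeric(1))
}

# clustering by explicit triangle loops (binary) / Onnela loops (weighted)
oracle_clustering <- function(adj, weighted) {
  R <- ncol(adj)
  out <- numeric(R)
  W <- if (weighted && max(adj) > 0) adj / max(adj) else (adj > 0) * 1
  for (i in seq_len(R)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (a in nb) for (b in nb) {
      if (a != b && adj[a, b] > 0) {
        s <- s + (W[i, a] * W[i, b] * W[a, b])^(1 / 3)
      }
    }
    out[i] <- s / (k * (k - 1))
  }
  out
}

oracle_eloc <- function(adj, weighted) {
  R <- ncol(adj)
  vapply(seq_len(R), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_eglob(adj[nb, nb, drop = FALSE], weighted)
  }, numeric(1))
}

# betweenness by exhaustive simple-path enumeration: for every pair, list
# all simple paths, keep the shortest-length ones, and count the fraction
# through each interior node
oracle_betweenness <- function(adj, weighted) {
  R <- ncol(adj)
  all_paths <- function(from, to) {
    paths <- list()
    walk <- function(path, len) {
      last <- path[length(path)]
      if (last == to) {
        paths[[length(paths) + 1]] <<- list(path = path, len = len)
        return()
      }
      for (nxt in which(adj[last, ] > 0)) {
        if (nxt %in% path) next
        step <- if (weighted) 1 / adj[last, nxt] else 1
        walk(c(path, nxt), len + step)
      }
    }
    walk(from, 0)
    paths
  }
  bc <- numeric(R)
  for (i in seq_len(R - 1)) for (j in (i + 1):R) {
    ps <- all_paths(i, j)
    if (length(ps) == 0) next
    lens <- vapply(ps, `[[`, numeric(1), "len")
    short <- ps[abs(lens - min(lens)) < 1e-12]
    for (v in seq_len(R)) {
      if (v == i || v == j) next
      hit <- sum(vapply(short, function(p) v %in% p$path, logical(1)))
      bc[v] <- bc[v] + hit / length(short)
    }
  }
  bc / ((R - 1) * (R - 2) / 2)
}

# Newman modularity of a given partition, straight from the definition
oracle_modularity <- function(adj, membership) {
  m2 <- sum(adj)        # 2m for undirected stored symmetrically
  if (m2 == 0) return(0)
  k <- rowSums(adj)
  q <- 0
  R <- ncol(adj)
  for (i in seq_len(R)) for (j in seq_len(R)) {
    if (membership[i] == membership[j]) {
      q <- q + adj[i, j] - k[i] * k[j] / m2
    }
  }
  q / m2
}

# random small test graphs
random_adjacency <- function(R, density = 0.5, weighted = TRUE) {
  A <- matrix(0, R, R)
  up <- which(upper.tri(A))
  on <- runif(length(up)) < density
  A[up[on]] <- if (weighted) runif(sum(on), 0.1, 1) else 1
  A + t(A)
}

# two-class Gaussian feature data with planted mean shifts
planted_class_data <- function(n_per_class, p, shift_cols = integer(0), d = 0,
                               seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
  y <- factor(rep(c("TD", "ADHD"), each = n_per_class), levels = c("TD", "ADHD"))
  for (j in shift_cols) X[y == "ADHD", j] <- X[y == "ADHD", j] + d
  list(X = X, y = y)
}

small_site_counts <- function(n_td = c(12, 10), n_c = c(6, 4), n_i = c(2, 4),
                              n_h = c(0, 0), sites = c("SiteA", "SiteB")) {
  data.frame(site = sites, n_td = n_td, n_adhd_c = n_c, n_adhd_h = n_h,
             n_adhd_i = n_i)
}
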