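# Graph-theoretical network metrics. Definitions follow the standard
# brain-connectivity formulations: binarized clustering by triangle counting,
# weighted clustering by the Onnela geometric-mean rule, efficiency as mean
# inverse shortest-path length, local/regional efficiency per node, and
# betweenness as the fraction of all-pairs shortest paths through a node.
# Shortest paths on weighted graphs use the inverse-weight length 1/w.

nodal_clustering <- function(g) {
  A <- g$adj
  R <- ncol(A)
  k <- rowSums(A > 0)
  cc <- numeric(R)
  if (g$mode == "binarized") {
    B <- (A > 0) * 1
    t3 <- diag(B %*% B %*% B)
    ok <- k >= 2
    cc[ok] <- t3[ok] / (k[ok] * (k[ok] - 1))
  } else {
    if (max(A) > 0) {
      W <- (A / max(A))^(1 / 3)
      t3 <- diag(W %*% W %*% W)
      ok <- k >= 2
      cc[ok] <- t3[ok] / (k[ok] * (k[ok] - 1))
    }
  }
  names(cc) <- g$roi_names
  cc
}

efficiency_from_distances <- function(D) {
  iD <- 1 / D
  diag(iD) <- 0
  iD[!is.finite(iD)] <- 0
  iD
}

nodal_local_efficiency <- function(g) {
  A <- g$adj
  R <- ncol(A)
  el <- numeric(R)
  for (i in seq_len(R)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) next
    sub <- structure(list(adj = A[nb, nb, drop = FALSE], mode = g$mode,
                          sparsity = NA_real_,
                          roi_names = g$roi_names[nb]), class = "brain_graph")
    iD <- efficiency_from_distances(graph_distances(sub))
    el[i] <- sum(iD) / (length(nb) * (length(nb) - 1))
  }
  names(el) <- g$roi_names
  el
}

#' Global graph metrics
#'
#' Computes the global network measures of a thresholded brain graph:
#' clustering coefficient `cc` (mean nodal clustering), local efficiency
#' `eloc` (mean nodal local efficiency), characteristic path length `cpl`
#' (mean shortest-path length over connected pairs; `Inf` with a
#' `disconnected` flag when no pair is connected), global efficiency `eglob`
#' (mean inverse shortest-path length over all pairs), and modularity `q` of
#' the best Louvain partition found (best of `louvain_restarts` seeded
#' restarts; only the value of Q, not the labels, is a stable feature).
#'
#' @param g A `brain_graph` with at least 3 nodes.
#' @param louvain_restarts Number of seeded Louvain restarts.
#' @param seed Seed for the Louvain restarts.
#' @return Named list with `cc`, `eloc`, `cpl`, `eglob`, `q`, and logical
#'   `disconnected`.
#' @export
global_graph_metrics <- function(g, louvain_restarts = 5, seed = 1) {
  stopifnot(inherits(g, "brain_graph"))
  if (ncol(g$adj) < 3) stop("need at least 3 nodes")
  D <- graph_distances(g)
  off <- D[upper.tri(D)]
  finite <- off[is.finite(off) & off > 0]
  cpl <- if (length(finite)) mean(finite) else Inf
  iD <- efficiency_from_distances(D)
  R <- ncol(D)
  eglob <- sum(iD) / (R * (R - 1))
  cc <- mean(nodal_clustering(g))
  eloc <- mean(nodal_local_efficiency(g))
  q <- louvain_modularity(g, restarts = louvain_restarts, seed = seed)
  list(cc = cc, eloc = eloc, cpl = cpl, eglob = eglob, q = q,
       disconnected = any(!is.finite(off)))
}

louvain_modularity <- function(g, restarts = 5, seed = 1) {
  ig <- brain_graph_igraph(g)
  if (igraph::ecount(ig) == 0) return(0)
  w <- igraph::E(ig)$weight
  best <- -Inf
  for (r in seq_len(restarts)) {
    cm <- with_seed(derive_seed(seed, paste0("louvain", r)),
                    igraph::cluster_louvain(ig, weights = w))
    q <- max(cm$modularity)
    if (q > best) best <- q
  }
  best
}

#' Nodal graph metrics
#'
#' Per-node measures: `strength` (sum of connection weights; equals degree on
#' binarized graphs), `degree` (number of connections), clustering `cc`,
#' local efficiency `eloc`, regional efficiency `ereg` (mean inverse
#' shortest-path length from the node to every other node), and betweenness
#' centrality `bc` (fraction of all-pairs shortest paths through the node,
#' normalized by `(R-1)(R-2)/2`). Isolated nodes score 0 on all measures.
#'
#' @param g A `brain_graph` with at least 3 nodes.
#' @return Data frame with one row per node.
#' @export
nodal_graph_metrics <- function(g) {
  stopifnot(inherits(g, "brain_graph"))
  R <- ncol(g$adj)
  if (R < 3) stop("need at least 3 nodes")
  D <- graph_distances(g)
  iD <- efficiency_from_distances(D)
  ig <- brain_graph_igraph(g)
  w <- if (g$mode == "weighted" && igraph::ecount(ig) > 0) 1 / igraph::E(ig)$weight else NULL
  bc <- igraph::betweenness(ig, weights = w, directed = FALSE)
  data.frame(
    roi = g$roi_names,
    strength = rowSums(g$adj),
    degree = rowSums(g$adj > 0),
    cc = nodal_clustering(g),
    eloc = nodal_local_efficiency(g),
    ereg = rowSums(iD) / (R - 1),
    bc = bc / ((R - 1) * (R - 2) / 2),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# degree-preserving rewired (or Erdos-Renyi) null realization of g
random_null_graph <- function(g, seed, null = c("rewire", "er")) {
  null <- match.arg(null)
  ig <- brain_graph_igraph(g)
  ne <- igraph::ecount(ig)
  if (ne == 0) return(g)
  with_seed(seed, {
    if (null == "rewire") {
      rg <- igraph::rewire(ig, igraph::keeping_degseq(niter = 10 * ne))
    } else {
      rg <- igraph::sample_gnm(igraph::vcount(ig), ne)
    }
    adj <- matrix(0, ncol(g$adj), ncol(g$adj), dimnames = dimnames(g$adj))
    el <- igraph::as_edgelist(rg, names = FALSE)
    wts <- if (g$mode == "weighted") sample(igraph::E(ig)$weight) else rep(1, ne)
    adj[el] <- wts
    adj <- adj + t(adj)
    structure(list(adj = adj, mode = g$mode, sparsity = g$sparsity,
                   roi_names = g$roi_names), class = "brain_graph")
  })
}

#' Random-network normalized clustering, path length and small-worldness
#'
#' `gamma` is the ratio of the graph's clustering coefficient to the mean
#' clustering of `n_random` simulated random networks with equivalent
#' numbers of nodes and edges; `lambda` the same ratio for characteristic
#' path length; `sigma = gamma / lambda` is small-worldness. The null
#' ensemble is degree-preserving edge rewiring (10 swaps per edge) by
#' default; an Erdos-Renyi ensemble with matched node and edge counts is
#' available via `null = "er"`. Weighted graphs permute the original edge
#' weights onto the rewired topology. Deterministic given `seed`.
#'
#' @param g A `brain_graph` with finite characteristic path length.
#' @param n_random Ensemble size (default 100).
#' @param seed Integer seed.
#' @param null `"rewire"` (default) or `"er"`.
#' @return Named list `gamma`, `lambda`, `sigma` plus ensemble summaries
#'   `cc_rand`, `cpl_rand` (means) and their standard deviations. `gamma` is
#'   `NA` with a warning if the random ensemble has zero clustering.
#' @export
normalized_metrics <- function(g, n_random = 100, seed = 1,
                               null = c("rewire", "er")) {
  null <- match.arg(null)
  stopifnot(inherits(g, "brain_graph"))
  D <- graph_distances(g)
  off <- D[upper.tri(D)]
  cpl <- mean(off[is.finite(off) & off > 0])
  cc <- mean(nodal_clustering(g))
  cc_r <- cpl_r <- numeric(n_random)
  for (b in seq_len(n_random)) {
    rg <- random_null_graph(g, seed = derive_seed(seed, paste0("null", b)),
                            null = null)
    Dr <- graph_distances(rg)
    offr <- Dr[upper.tri(Dr)]
    cpl_r[b] <- mean(offr[is.finite(offr) & offr > 0])
    cc_r[b] <- mean(nodal_clustering(rg))
  }
  mean_cc_r <- mean(cc_r)
  mean_cpl_r <- mean(cpl_r)
  gamma <- if (mean_cc_r > 0) cc / mean_cc_r else {
    warning("random ensemble has zero clustering; gamma undefined")
    NA_real_
  }
  lambda <- cpl / mean_cpl_r
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       cc_rand = mean_cc_r, cpl_rand = mean_cpl_r,
       cc_rand_sd = stats::sd(cc_r), cpl_rand_sd = stats::sd(cpl_r))
}

#' Graph metrics averaged across sparsity levels
#'
#' Thresholds a connectivity matrix at each sparsity level (default 10, 15,
#' 20, 25 and 30 percent), computes the eight global metrics (clustering,
#' local efficiency, characteristic path length, global efficiency, gamma,
#' lambda, small-worldness, modularity) and the five nodal metrics
#' (strength, clustering, local efficiency, regional efficiency,
#' betweenness) at each level, and returns their arithmetic means across
#' levels. Non-finite values (e.g. path length of a disconnected level) are
#' excluded from the mean with a warning.
#'
#' @param m A `connectivity_matrix`.
#' @param levels Sparsity levels (default `c(.10, .15, .20, .25, .30)`).
#' @param mode `"weighted"` or `"binarized"`.
#' @param n_random Random-ensemble size for gamma/lambda/sigma; `0` skips
#'   the normalized metrics.
#' @param seed Integer seed for the normalization ensembles.
#' @return Named numeric vector of averaged metrics: `global_*` and
#'   `nodal_<metric>_<roi>`. The per-level values are attached as attribute
#'   `"by_level"`.
#' @export
metrics_across_sparsities <- function(m, levels = c(0.10, 0.15, 0.20, 0.25, 0.30),
                                      mode = c("weighted", "binarized"),
                                      n_random = 100, seed = 1) {
  mode <- match.arg(mode)
  per_level <- lapply(seq_along(levels), function(li) {
    g <- threshold_proportional(m, levels[li], mode = mode)
    gm <- global_graph_metrics(g, seed = derive_seed(seed, paste0("q", li)))
    nm <- nodal_graph_metrics(g)
    out <- c(global_cc = gm$cc, global_eloc = gm$eloc, global_cpl = gm$cpl,
             global_eglob = gm$eglob, global_q = gm$q)
    if (n_random > 0) {
      nz <- normalized_metrics(g, n_random = n_random,
                               seed = derive_seed(seed, paste0("norm", li)))
      out <- c(out, global_gamma = nz$gamma, global_lambda = nz$lambda,
               global_sigma = nz$sigma)
    }
    nodal <- c(
      stats::setNames(nm$strength, paste0("nodal_strength_", nm$roi)),
      stats::setNames(nm$cc, paste0("nodal_cc_", nm$roi)),
      stats::setNames(nm$eloc, paste0("nodal_eloc_", nm$roi)),
      stats::setNames(nm$ereg, paste0("nodal_ereg_", nm$roi)),
      stats::setNames(nm$bc, paste0("nodal_bc_", nm$roi))
    )
    c(out, nodal)
  })
  tab <- do.call(rbind, per_level)
  bad <- !is.finite(tab)
  if (any(bad)) {
    warning("non-finite metric values at some sparsity levels excluded from the average")
    tab[bad] <- NA_real_
  }
  avg <- colMeans(tab, na.rm = TRUE)
  avg[is.nan(avg)] <- NA_real_
  attr(avg, "by_level") <- cbind(sparsity = levels, tab)
  avg
}
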