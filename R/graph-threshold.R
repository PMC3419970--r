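#' Proportional thresholding of a connectivity matrix
#'
#' Network sparsity is normalized across subjects by retaining the same
#' fraction `p` of each subject's strongest *positive* connections:
#' `round(p * R(R-1)/2)` edges. Negative values are always discarded. If the
#' matrix has fewer positive entries than requested, all positives are kept
#' with a warning. Ties are broken deterministically by (weight descending,
#' row ascending, column ascending).
#'
#' @param m A `connectivity_matrix` (or symmetric matrix of weights).
#' @param p Sparsity in `(0, 1]`.
#' @param mode `"weighted"` (retain Fisher-z weights) or `"binarized"`.
#' @return An object of class `brain_graph`: list with `adj` (symmetric
#'   nonnegative adjacency, zero diagonal), `mode`, `sparsity`, `roi_names`.
#' @export
threshold_proportional <- function(m, p, mode = c("weighted", "binarized")) {
  mode <- match.arg(mode)
  if (!(p > 0 && p <= 1)) stop("sparsity p must be in (0, 1]")
  if (inherits(m, "connectivity_matrix")) {
    z <- m$z
    rois <- m$roi_names
  } else {
    z <- as.matrix(m)
    rois <- colnames(z) %||% sprintf("roi_%03d", seq_len(ncol(z)))
    diag(z) <- 0
  }
  R <- ncol(z)
  idx <- which(upper.tri(z), arr.ind = TRUE)
  w <- z[upper.tri(z)]
  pos <- w > 0
  target <- round(p * R * (R - 1) / 2)
  if (sum(pos) < target) {
    warning("only ", sum(pos), " positive connections available; keeping all")
    target <- sum(pos)
  }
  ord <- order(-w, idx[, "row"], idx[, "col"])
  ord <- ord[pos[ord]][seq_len(target)]
  adj <- matrix(0, R, R, dimnames = list(rois, rois))
  keep <- cbind(idx[ord, , drop = FALSE])
  adj[keep] <- if (mode == "binarized") 1 else w[ord]
  adj <- adj + t(adj)
  structure(list(adj = adj, mode = mode, sparsity = p, roi_names = rois),
            class = "brain_graph")
}

#' Construct a brain graph from an adjacency matrix
#'
#' @param adj Symmetric nonnegative matrix with zero diagonal.
#' @param mode `"weighted"` or `"binarized"`.
#' @return A `brain_graph`.
#' @export
as_brain_graph <- function(adj, mode = c("weighted", "binarized")) {
  mode <- match.arg(mode)
  adj <- as.matrix(adj)
  stopifnot(nrow(adj) == ncol(adj))
  if (max(abs(adj - t(adj))) > 1e-10) stop("adjacency must be symmetric")
  if (any(adj < 0)) stop("adjacency must be nonnegative")
  diag(adj) <- 0
  rois <- colnames(adj) %||% sprintf("roi_%03d", seq_len(ncol(adj)))
  dimnames(adj) <- list(rois, rois)
  if (mode == "binarized") adj <- (adj > 0) * 1
  structure(list(adj = adj, mode = mode, sparsity = NA_real_,
                 roi_names = rois), class = "brain_graph")
}

brain_graph_igraph <- function(g) {
  ig <- igraph::graph_from_adjacency_matrix(g$adj, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  ig
}

# shortest-path distance matrix: binarized graphs use hop counts, weighted
# graphs use d_ij = 1/w_ij (standard for connectivity weights)
graph_distances <- function(g) {
  ig <- brain_graph_igraph(g)
  w <- if (g$mode == "weighted" && igraph::ecount(ig) > 0) {
    1 / igraph::E(ig)$weight
  } else {
    NULL
  }
  igraph::distances(ig, weights = w)
}
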