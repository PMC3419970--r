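#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded stages do not perturb the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed
#'
#' Every randomized stage of the pipeline draws its own seed from the run's
#' master seed and a stage tag, via a small documented integer hash:
#' `(master * 2654435 + sum_i i * utf8(tag)_i) mod (2^31 - 1)`.
#' This keeps stages independently re-runnable and all seeds below 2^31.
#'
#' @param master Integer master seed.
#' @param tag Character stage tag.
#' @return An integer seed.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(tag))
  codes <- utf8ToInt(paste(tag, collapse = "/"))
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(master)) * 2654435 + h) %% (2^31 - 1))
}

#' Stratified fold assignment
#'
#' Assigns each observation to one of `k` folds, stratified by class so that
#' every fold contains both classes whenever counts allow.
#'
#' @param y Factor (or coercible) of class labels.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold ids in `1:k`, one per observation.
#' @export
stratified_folds <- function(y, k, seed = 1) {
  y <- as.factor(y)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# column standardization parameters computed on (and only on) the rows given;
# zero-variance columns get scale 1 so they standardize to constant 0
scaling_params <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scaling <- function(X, prm) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, prm$center, "-"), 2, prm$scale, "/")
}

#' Round half away from zero
#'
#' Prevalence percentages are reported rounded to the nearest integer (or to
#' one decimal for table cells) with halves rounded away from zero, the
#' convention that reproduces the printed demographic summaries
#' (e.g. 285/776 -> 37, 45/52 -> 86.5).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Collapse the four-level diagnosis to the two-class problem
#'
#' @param dx Vector of diagnosis labels.
#' @return Factor with levels `TD`, `ADHD` (all subtypes collapse to ADHD).
#' @export
collapse_dx <- function(dx) {
  factor(ifelse(as.character(dx) == "TD", "TD", "ADHD"), levels = c("TD", "ADHD"))
}

#' The four diagnosis levels
#'
#' @return `c("TD", "ADHD-C", "ADHD-H", "ADHD-I")`.
#' @export
dx_levels <- function() c("TD", "ADHD-C", "ADHD-H", "ADHD-I")

`%||%` <- function(a, b) if (is.null(a)) b else a
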