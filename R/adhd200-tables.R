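# The published ADHD-200 training-set composition. These printed counts are
# inputs to the demographic analyses and to the default synthetic-cohort
# configuration; they are stored as code so the package carries no data
# files.

#' ADHD-200 training-set subject counts by site and diagnosis
#'
#' @return Data frame with columns `site`, `n_td`, `n_adhd_c`, `n_adhd_h`,
#'   `n_adhd_i` for the seven training sites (total 776 subjects: 491 TD,
#'   163 ADHD-C, 11 ADHD-H, 111 ADHD-I).
#' @export
adhd200_site_counts <- function() {
  data.frame(
    site     = c("Peking", "KKI", "NI", "NYU", "OHSU", "Pitt", "WashU"),
    n_td     = c(116, 61, 23, 99, 42, 89, 61),
    n_adhd_c = c(29, 16, 18, 77, 23, 0, 0),
    n_adhd_h = c(0, 1, 6, 2, 2, 0, 0),
    n_adhd_i = c(49, 5, 1, 44, 12, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' ADHD-200 training-set subject counts by site, diagnosis and gender
#'
#' Covers the five sites with ADHD training subjects; ADHD-H is not broken
#' out by gender in the published table and is omitted here.
#'
#' @return Data frame with columns `site`, `gender`, `n_td`, `n_adhd_c`,
#'   `n_adhd_i`.
#' @export
adhd200_gender_counts <- function() {
  data.frame(
    site     = rep(c("Peking", "KKI", "NI", "NYU", "OHSU"), times = 2),
    gender   = rep(c("F", "M"), each = 5),
    n_td     = c(45, 27, 12, 52, 24,   71, 34, 11, 47, 18),
    n_adhd_c = c(0, 9, 4, 12, 4,       29, 7, 14, 64, 19),
    n_adhd_i = c(7, 1, 0, 15, 6,       42, 4, 1, 29, 6),
    stringsAsFactors = FALSE
  )
}

# expand a wide count table into one phenotype row per subject
expand_counts <- function(counts, count_cols, dx_labels, extra_cols = "site") {
  rows <- list()
  for (r in seq_len(nrow(counts))) {
    for (k in seq_along(count_cols)) {
      n <- counts[[count_cols[k]]][r]
      if (n == 0) next
      block <- counts[rep(r, n), extra_cols, drop = FALSE]
      block$dx <- dx_labels[k]
      rows[[length(rows) + 1]] <- block
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$dx <- factor(out$dx, levels = dx_levels())
  out
}

#' Expand the site count table to a subject-level phenotype table
#'
#' @param counts A table as returned by [adhd200_site_counts()].
#' @return Data frame with one row per subject (`site`, `dx`).
#' @export
expand_site_counts <- function(counts = adhd200_site_counts()) {
  expand_counts(counts, c("n_td", "n_adhd_c", "n_adhd_h", "n_adhd_i"),
                c("TD", "ADHD-C", "ADHD-H", "ADHD-I"))
}

#' Expand the gender count table to a subject-level phenotype table
#'
#' @param counts A table as returned by [adhd200_gender_counts()].
#' @return Data frame with one row per subject (`site`, `gender`, `dx`).
#' @export
expand_gender_counts <- function(counts = adhd200_gender_counts()) {
  expand_counts(counts, c("n_td", "n_adhd_c", "n_adhd_i"),
                c("TD", "ADHD-C", "ADHD-I"), extra_cols = c("site", "gender"))
}
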