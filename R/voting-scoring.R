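#' Majority vote over modality predictions
#'
#' The most common class among a subject's modality-level predictions
#' becomes the final two-class label. Ties resolve to `tie` (default
#' `"TD"`: the sample is majority TD and correct TD calls carry full
#' weight in the competition scoring). Voting is invariant to the order of
#' the votes.
#'
#' @param votes Character vector of two-class votes (at least one).
#' @param tie Label returned on a tie.
#' @return A single label.
#' @export
majority_vote <- function(votes, tie = "TD") {
  votes <- as.character(votes)
  if (length(votes) == 0) stop("empty vote set")
  tab <- sort(table(votes), decreasing = TRUE)
  winners <- names(tab)[tab == tab[1]]
  if (length(winners) > 1) tie else winners[1]
}

#' Site-specific ADHD subtype assignment
#'
#' Subjects predicted ADHD are assigned the most common ADHD subtype
#' (`ADHD-C` or `ADHD-I`) among that site's ADHD training subjects -- the
#' site-specific pretest probability. Ties resolve to `ADHD-C` (the more
#' prevalent subtype overall). A site with no ADHD training subjects falls
#' back to the pooled modal subtype, with a message.
#'
#' @param site Site name.
#' @param phenotypes Training phenotype table with columns `site` and `dx`.
#' @return `"ADHD-C"` or `"ADHD-I"`.
#' @export
assign_subtype <- function(site, phenotypes) {
  sub <- phenotypes[phenotypes$dx %in% c("ADHD-C", "ADHD-I"), , drop = FALSE]
  at_site <- sub[sub$site == site, , drop = FALSE]
  if (nrow(at_site) == 0) {
    message("no ADHD training subjects at site ", site,
            "; using pooled modal subtype")
    at_site <- sub
  }
  if (nrow(at_site) == 0) return("ADHD-C")
  n_c <- sum(at_site$dx == "ADHD-C")
  n_i <- sum(at_site$dx == "ADHD-I")
  if (n_i > n_c) "ADHD-I" else "ADHD-C"
}

#' Score three-class predictions with the competition metrics
#'
#' Computes the competition-style performance report: three-class accuracy
#' (exact match among TD / ADHD-C / ADHD-I), two-class sensitivity
#' (fraction of true ADHD predicted ADHD) and specificity (fraction of true
#' TD predicted TD), subtype accuracy (fraction of true-ADHD subjects
#' predicted ADHD whose subtype is also correct), and points. The default
#' point scheme awards 1 for a correct TD, 1 for a correct ADHD call with
#' correct subtype, 0.5 for a correct ADHD call with the wrong subtype and
#' 0 otherwise, so the maximum equals the number of subjects and half
#' points are possible.
#'
#' @param pred Data frame with columns `subject_id` and `label` (three-class
#'   prediction).
#' @param truth Data frame with columns `subject_id` and `dx` (true
#'   three-class labels; `ADHD-H` rows, if any, count as ADHD for the
#'   two-class metrics and can never match a predicted subtype).
#' @param points_scheme Named numeric vector with elements `correct_td`,
#'   `correct_subtype`, `wrong_subtype`, `wrong`.
#' @return Object of class `score_report`: list with `accuracy_3class`,
#'   `sensitivity`, `specificity`, `subtype_accuracy`, `points`,
#'   `max_points`, `n`.
#' @export
score_predictions <- function(pred, truth,
                              points_scheme = c(correct_td = 1,
                                                correct_subtype = 1,
                                                wrong_subtype = 0.5,
                                                wrong = 0)) {
  pred <- as.data.frame(pred)
  truth <- as.data.frame(truth)
  if (!setequal(pred$subject_id, truth$subject_id) ||
      nrow(pred) != nrow(truth)) {
    stop("prediction and truth tables must cover the same subjects")
  }
  truth <- truth[match(pred$subject_id, truth$subject_id), ]
  p <- as.character(pred$label)
  t3 <- as.character(truth$dx)
  p2 <- ifelse(p == "TD", "TD", "ADHD")
  t2 <- ifelse(t3 == "TD", "TD", "ADHD")
  acc3 <- mean(p == t3)
  sens <- if (any(t2 == "ADHD")) mean(p2[t2 == "ADHD"] == "ADHD") else NA_real_
  spec <- if (any(t2 == "TD")) mean(p2[t2 == "TD"] == "TD") else NA_real_
  adhd_hit <- t2 == "ADHD" & p2 == "ADHD"
  subtype_acc <- if (any(adhd_hit)) mean(p[adhd_hit] == t3[adhd_hit]) else NA_real_
  pts <- vapply(seq_along(p), function(i) {
    if (t2[i] == "TD") {
      if (p2[i] == "TD") points_scheme[["correct_td"]] else points_scheme[["wrong"]]
    } else if (p2[i] == "ADHD") {
      if (p[i] == t3[i]) points_scheme[["correct_subtype"]] else points_scheme[["wrong_subtype"]]
    } else {
      points_scheme[["wrong"]]
    }
  }, numeric(1))
  structure(list(accuracy_3class = acc3, sensitivity = sens,
                 specificity = spec, subtype_accuracy = subtype_acc,
                 points = sum(pts), max_points = length(p), n = length(p)),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("3-class accuracy: %.3f\n", x$accuracy_3class))
  cat(sprintf("sensitivity:      %.3f\n", x$sensitivity))
  cat(sprintf("specificity:      %.3f\n", x$specificity))
  cat(sprintf("subtype accuracy: %.3f\n", x$subtype_accuracy))
  cat(sprintf("points:           %.1f / %d\n", x$points, x$max_points))
  invisible(x)
}

#' ADHD prevalence statistics of a phenotype table
#'
#' ADHD prevalence (non-TD fraction) per stratum, as percentages rounded
#' half away from zero -- the convention of the printed demographic
#' summaries (nearest integer by default, one decimal for table-style
#' cells).
#'
#' @param phenotypes Phenotype table with columns `site`, `dx`, and (for
#'   gender strata) `gender`.
#' @param by `"overall"`, `"site"`, `"gender"`, or `"site_gender"`.
#' @param include_adhd_h Count ADHD-H subjects (default `TRUE`); when
#'   `FALSE` they are removed before any counting, mirroring their
#'   exclusion from prediction.
#' @param exclude_td_only_sites Drop sites whose training data contain no
#'   ADHD subjects before computing prevalence (default `FALSE`).
#' @param digits Decimal places of the percentage (default 0).
#' @return Data frame with columns naming the stratum plus `n`, `n_adhd`,
#'   `prevalence_pct`.
#' @export
prevalence_stats <- function(phenotypes,
                             by = c("overall", "site", "gender", "site_gender"),
                             include_adhd_h = TRUE,
                             exclude_td_only_sites = FALSE,
                             digits = 0) {
  by <- match.arg(by)
  ph <- as.data.frame(phenotypes)
  if (nrow(ph) == 0) stop("empty phenotype table")
  if (!include_adhd_h) ph <- ph[ph$dx != "ADHD-H", , drop = FALSE]
  if (exclude_td_only_sites) {
    keep <- vapply(split(ph$dx != "TD", ph$site), any, logical(1))
    ph <- ph[ph$site %in% names(keep)[keep], , drop = FALSE]
  }
  strata <- switch(by,
    overall = list(overall = rep("all", nrow(ph))),
    site = list(site = ph$site),
    gender = list(gender = ph$gender),
    site_gender = list(site = ph$site, gender = ph$gender))
  agg <- stats::aggregate(ph$dx != "TD", by = strata,
                          FUN = function(x) c(n = length(x), n_adhd = sum(x)))
  out <- data.frame(agg[setdiff(names(agg), "x")],
                    n = agg$x[, "n"], n_adhd = agg$x[, "n_adhd"])
  out$prevalence_pct <- round_half_up(100 * out$n_adhd / out$n, digits)
  out
}

#' ADHD subtype ratio at a site
#'
#' The ratio of ADHD-C to ADHD-I training subjects, reduced by their
#' greatest common divisor (18:1 at a NI-like site, close to 3:5 at a
#' Peking-like site).
#'
#' @param phenotypes Phenotype table with `site` and `dx`.
#' @param site Site name.
#' @return Named integer vector `c(adhd_c = ..., adhd_i = ...)`.
#' @export
subtype_ratio <- function(phenotypes, site) {
  ph <- phenotypes[phenotypes$site == site, , drop = FALSE]
  n_c <- sum(ph$dx == "ADHD-C")
  n_i <- sum(ph$dx == "ADHD-I")
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  g <- max(1, gcd(n_c, n_i))
  c(adhd_c = as.integer(n_c / g), adhd_i = as.integer(n_i / g))
}
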