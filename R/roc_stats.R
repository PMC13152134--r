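#' Mann-Whitney AUC
#'
#' The area under the ROC curve as the Mann-Whitney probability that a
#' random positive scores above a random negative, with ties counted 1/2.
#'
#' @param scores numeric vector of classifier scores.
#' @param labels 0/1 vector, same length (1 = positive/abnormal).
#' @return the AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- check_binary_labels(scores, labels)
  mean(placement_pos(scores, labels))
}

check_binary_labels <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1", call. = FALSE)
  if (sum(labels == 1L) < 1L || sum(labels == 0L) < 1L)
    stop("undefined AUC: need at least one positive and one negative",
         call. = FALSE)
  labels
}

# Placement values ("structural components"): for each positive, the
# fraction of negatives it outranks (ties 1/2); computed from midranks in
# O(n log n). mean(placements) is the AUC.
placement_pos <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  (r_all[seq_len(m)] - r_pos) / n
}

placement_pos_raw_neg <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(neg, pos), ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  (r_all[seq_len(n)] - r_neg) / m
}

#' AUC with DeLong variance and confidence interval
#'
#' Nonparametric AUC variance from DeLong's per-positive and per-negative
#' placement values; the CI is the normal approximation truncated to
#' `[0, 1]`. Degenerate zero-variance cases (e.g. perfect separation)
#' return a point interval with a warning rather than failing, since they
#' genuinely occur in audit settings.
#'
#' @inheritParams auc_mann_whitney
#' @param level confidence level, default 0.95.
#' @return an object of class `roc_result`: list with `auc`, `variance`,
#'   `ci_low`, `ci_high`, `n_pos`, `n_neg`, `level`, and the placement
#'   values needed by the comparison tests.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  labels <- check_binary_labels(scores, labels)
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  if (m < 2L || n < 2L)
    stop("DeLong variance undefined: need at least 2 positives and 2 negatives",
         call. = FALSE)
  v10 <- placement_pos(scores, labels)         # per-positive
  v01 <- 1 - placement_pos_raw_neg(scores, labels)  # per-negative
  auc <- mean(v10)
  variance <- stats::var(v10) / m + stats::var(v01) / n
  if (variance <= 0) {
    variance <- 0
    warning("zero DeLong variance (degenerate scores); returning point CI",
            call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(variance)
  structure(list(auc = auc, variance = variance,
                 ci_low = max(0, auc - half), ci_high = min(1, auc + half),
                 n_pos = m, n_neg = n, level = level,
                 v10 = v10, v01 = v01),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.0f%% CI %.3f, %.3f), DeLong var %.2e, n+=%d n-=%d\n",
              x$auc, 100 * x$level, x$ci_low, x$ci_high, x$variance,
              x$n_pos, x$n_neg))
  invisible(x)
}

p_from_z <- function(z, alternative) {
  switch(alternative,
         greater   = stats::pnorm(z, lower.tail = FALSE),
         less      = stats::pnorm(z),
         two_sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
         stop("alternative must be greater, less or two_sided", call. = FALSE))
}

#' Unpaired DeLong comparison of two AUCs
#'
#' For AUCs estimated on disjoint samples: `z = (auc1 - auc2) /
#' sqrt(var1 + var2)` against the standard normal. The orientation for
#' leakage audits is `alternative = "greater"` with the with-duplicates
#' subset as `r1`.
#'
#' @param r1,r2 `roc_result` objects from disjoint samples.
#' @param alternative `"greater"` (auc1 > auc2), `"less"`, or `"two_sided"`.
#' @return the p-value.
#' @export
delong_test_unpaired <- function(r1, r2, alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(r1, "roc_result"), inherits(r2, "roc_result"))
  vsum <- r1$variance + r2$variance
  d <- r1$auc - r2$auc
  if (vsum == 0) {
    if (d == 0) {
      warning("degenerate comparison: equal AUCs with zero variance", call. = FALSE)
      return(1)
    }
    ok <- switch(alternative, greater = d > 0, less = d < 0, two_sided = TRUE)
    return(if (ok) 0 else 1)
  }
  p_from_z(d / sqrt(vsum), alternative)
}

#' Paired DeLong comparison of two score vectors
#'
#' Two models scored on the same samples: the variance of the AUC
#' difference uses the DeLong covariance of the two sets of placement
#' values.
#'
#' @param scores1,scores2 score vectors over the same samples.
#' @param labels shared 0/1 labels.
#' @param alternative as in [delong_test_unpaired()].
#' @return the p-value.
#' @export
delong_test_paired <- function(scores1, scores2, labels,
                               alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  labels <- check_binary_labels(scores1, labels)
  stopifnot(length(scores1) == length(scores2))
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  if (m < 2L || n < 2L)
    stop("DeLong variance undefined: need at least 2 positives and 2 negatives",
         call. = FALSE)
  d10 <- placement_pos(scores1, labels) - placement_pos(scores2, labels)
  d01 <- placement_pos_raw_neg(scores2, labels) - placement_pos_raw_neg(scores1, labels)
  d <- mean(d10)
  v <- stats::var(d10) / m + stats::var(d01) / n
  if (v <= 0) {
    if (abs(d) < .Machine$double.eps^0.5) return(1)
    ok <- switch(alternative, greater = d > 0, less = d < 0, two_sided = TRUE)
    return(if (ok) 0 else 1)
  }
  p_from_z(d / sqrt(v), alternative)
}
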