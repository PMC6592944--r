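# Evaluation metrics: F1, Mann-Whitney AUC, DeLong comparison of correlated
# AUCs, and stratified percentile bootstrap confidence intervals.

# coerce labels to 0/1 integer; exactly two classes required when check = TRUE
.binary_labels <- function(labels, check_both = TRUE) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  stopifnot(all(labels %in% c(0L, 1L)))
  if (check_both && length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  as.integer(labels)
}

#' F1 score from confusion counts
#'
#' Harmonic mean of precision `tp/(tp+fp)` and recall `tp/(tp+fn)`. By
#' convention the score is 0 whenever `tp = 0` (including the fully empty
#' case `tp = fp = fn = 0`).
#'
#' @param tp,fp,fn Nonnegative counts of true positives, false positives and
#'   false negatives.
#' @return F1 in `[0, 1]`.
#' @examples
#' f1_score(8, 2, 4)  # precision 0.8, recall 2/3
#' @export
f1_score <- function(tp, fp, fn) {
  tp <- .check_count(tp, "tp"); fp <- .check_count(fp, "fp")
  fn <- .check_count(fn, "fn")
  if (tp == 0L) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

# F1 of thresholded scores against binary labels
.f1_from_scores <- function(scores, labels, threshold) {
  pred <- scores >= threshold
  f1_score(sum(pred & labels == 1L), sum(pred & labels == 0L),
           sum(!pred & labels == 1L))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen positive observation is scored
#' above a randomly chosen negative one, with ties counted one half —
#' computed exactly via midranks.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (0/1, logical, or 2-level factor); both
#'   classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- .binary_labels(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: for each positive, the fraction of negatives it
# beats (ties = 1/2), and symmetrically for each negative.
.placements <- function(scores, labels) {
  x <- scores[labels == 1L]; y <- scores[labels == 0L]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yi) mean((x > yi) + 0.5 * (x == yi)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors computed on the same observations
#' (the paired design used when several vectorization methods score the same
#' test folds). The variance of the AUC difference is estimated from
#' placement values; the z statistic is referred to the standard normal for
#' a two-sided p-value. When the placement variance degenerates (e.g. both
#' score vectors identical) the test is inconclusive and p = 1 is returned
#' with a warning.
#'
#' @param scores_a,scores_b Score vectors from the two methods, same
#'   observations in the same order.
#' @param labels Shared binary labels.
#' @return An object of class `htest` with `statistic` (z), `p.value`, and
#'   `estimate` (the two AUCs).
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  labels <- .binary_labels(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  pa <- .placements(scores_a, labels)
  pb <- .placements(scores_b, labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  if (!is.finite(v) || v <= .Machine$double.eps) {
    warning("degenerate placement variance; DeLong test inconclusive (p = 1)")
    z <- 0
    p <- 1
  } else {
    z <- (pa$auc - pb$auc) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = c(z = z), p.value = p,
                 estimate = c(auc_a = pa$auc, auc_b = pb$auc),
                 method = "DeLong test for two correlated ROC curves (paired)",
                 data.name = "scores_a, scores_b by labels"),
            class = "htest")
}

#' Stratified percentile bootstrap confidence interval
#'
#' Resamples positives and negatives separately (so every resample retains
#' both classes) and returns the percentile interval of the metric across
#' `B` resamples. F1 is computed by thresholding the scores.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels, both classes present.
#' @param metric `"auc"` or `"f1"`.
#' @param B Number of resamples (at least 100).
#' @param alpha Two-sided miscoverage level; 0.05 gives a 95\% interval.
#' @param seed Integer seed.
#' @param threshold Classification threshold for F1 (default 0.5).
#' @return List with `lower`, `upper`, `point` (full-sample metric),
#'   `metric`, and `B`.
#' @export
bootstrap_ci <- function(scores, labels, metric = c("auc", "f1"), B = 2000L,
                         alpha = 0.05, seed = 1L, threshold = 0.5) {
  metric <- match.arg(metric)
  labels <- .binary_labels(labels)
  B <- .check_count(B, "B", 100L)
  ip <- which(labels == 1L); im <- which(labels == 0L)
  stat <- function(idx) {
    if (metric == "auc") auc_score(scores[idx], labels[idx])
    else .f1_from_scores(scores[idx], labels[idx], threshold)
  }
  vals <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      stat(c(sample(ip, length(ip), replace = TRUE),
             sample(im, length(im), replace = TRUE)))
    }, numeric(1))
  })
  q <- stats::quantile(vals, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  list(lower = q[1], upper = q[2], point = stat(seq_along(labels)),
       metric = metric, B = B)
}
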