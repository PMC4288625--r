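# Validation-set performance: ROC AUC, Youden-optimal threshold,
# confusion-matrix operating characteristics, and the Wilcoxon rank-sum
# association test.

#' ROC area under the curve
#'
#' Rank (Mann-Whitney) formulation; tied probabilities contribute 1/2.
#'
#' @param probs predicted probabilities (any real scores work).
#' @param labels class labels (see [as_binary_labels()]).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(probs, labels) {
  y <- as_binary_labels(labels)
  if (length(probs) != length(y)) stop("probs and labels differ in length")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(probs)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-optimal decision threshold
#'
#' Scans the observed probabilities as candidate thresholds under the
#' convention "call IPF when p >= t" and returns the threshold maximizing
#' J = sensitivity + specificity - 1. Ties are resolved toward the largest
#' threshold (the specificity-favoring cut).
#'
#' @inheritParams roc_auc
#' @return list with `threshold` and `j`.
#' @export
youden_threshold <- function(probs, labels) {
  y <- as_binary_labels(labels)
  if (length(probs) != length(y)) stop("probs and labels differ in length")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  cand <- sort(unique(probs), decreasing = TRUE)
  j <- vapply(cand, function(t) {
    sens <- sum(probs >= t & y == 1) / n1
    spec <- sum(probs < t & y == 0) / n0
    sens + spec - 1
  }, numeric(1))
  best <- which.max(j)  # candidates descend, so the first max is the largest t
  list(threshold = cand[best], j = j[best])
}

#' Confusion-matrix operating characteristics at a threshold
#'
#' Applies "p >= threshold -> IPF" and fills the confusion counts and derived
#' rates. Rates with an empty denominator are `NA`, never 0.
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold in [0, 1].
#' @return list with `confusion` (tp, fp, tn, fn) and `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy`.
#' @export
confusion_metrics <- function(probs, labels, threshold) {
  y <- as_binary_labels(labels)
  if (length(probs) != length(y)) stop("probs and labels differ in length")
  if (!(threshold >= 0 && threshold <= 1)) stop("threshold must lie in [0, 1]")
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  list(confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
       sensitivity = rate(tp, tp + fn),
       specificity = rate(tn, tn + fp),
       ppv = rate(tp, tp + fp),
       npv = rate(tn, tn + fn),
       accuracy = rate(tp + tn, tp + fp + tn + fn))
}

#' Wilcoxon rank-sum test of probability-phenotype association
#'
#' Two-sided. Exact enumeration when both groups have at most 10 samples and
#' there are no ties; otherwise the normal approximation with tie correction.
#'
#' @inheritParams roc_auc
#' @return the p-value.
#' @export
wilcoxon_rank_sum <- function(probs, labels) {
  y <- as_binary_labels(labels)
  if (length(probs) != length(y)) stop("probs and labels differ in length")
  a <- probs[y == 1]; b <- probs[y == 0]
  if (length(a) == 0 || length(b) == 0) stop("both classes must be present")
  ties <- anyDuplicated(probs) > 0
  use_exact <- length(a) <= 10 && length(b) <= 10 && !ties
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                       correct = !use_exact)$p.value
  )
}

#' Full validation performance report
#'
#' Computes AUC, the decision threshold (Youden-optimal unless a fixed value
#' is supplied), the confusion matrix and derived rates at that threshold,
#' and the Wilcoxon rank-sum p-value.
#'
#' @inheritParams roc_auc
#' @param threshold fixed threshold in [0, 1], or `NULL` (default) to use the
#'   Youden-optimal threshold computed from these predictions.
#' @return a `performance_report` list: `auc`, `threshold`,
#'   `threshold_source`, `youden_j`, confusion counts and rates,
#'   `wilcoxon_p`, `n_ipf`, `n_normal`.
#' @export
evaluate_performance <- function(probs, labels, threshold = NULL) {
  y <- as_binary_labels(labels)
  source <- if (is.null(threshold)) "youden" else "fixed"
  yj <- youden_threshold(probs, y)
  if (is.null(threshold)) threshold <- yj$threshold
  cm <- confusion_metrics(probs, y, threshold)
  structure(c(list(auc = roc_auc(probs, y),
                   threshold = threshold,
                   threshold_source = source,
                   youden_j = yj$j),
              cm,
              list(wilcoxon_p = wilcoxon_rank_sum(probs, y),
                   n_ipf = sum(y == 1), n_normal = sum(y == 0))),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("Validation performance (", x$n_ipf, " IPF vs ", x$n_normal, " normal)\n", sep = "")
  cat(sprintf("  AUC         %.3f\n", x$auc))
  cat(sprintf("  threshold   %.3f (%s)\n", x$threshold, x$threshold_source))
  fmt <- function(v) if (is.na(v)) "  NA" else sprintf("%3.0f%%", 100 * v)
  cat("  sensitivity", fmt(x$sensitivity), "\n")
  cat("  specificity", fmt(x$specificity), "\n")
  cat("  PPV        ", fmt(x$ppv), "\n")
  cat("  NPV        ", fmt(x$npv), "\n")
  cat("  accuracy   ", fmt(x$accuracy), "\n")
  cat(sprintf("  Wilcoxon p  %.2g\n", x$wilcoxon_p))
  invisible(x)
}
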