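## Ranking and threshold metrics for scored drug-disease pairs.

# ROC-AUC via the Mann-Whitney rank statistic with ties averaged
rocAuc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Area under the precision-recall curve, step-wise integration
# (precision held between recall points; tied scores processed as a block).
prAuc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0) stop("AUPR undefined: no positives")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  groups <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  # evaluate at the last index of each tie group
  last <- which(!duplicated(groups, fromLast = TRUE))
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / n1
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Threshold and ranking metrics for scored pairs
#'
#' Computes the confusion counts at a decision threshold plus the six
#' threshold metrics and the two ranking metrics. Raw decoder scores are
#' unbounded inner products, so by default they are min-max scaled to [0,1]
#' within the scored set before thresholding at 0.5; alternatively the
#' F1-maximizing threshold can be used. Ranking metrics (AUC from the rank
#' statistic with ties averaged; AUPR by step-wise precision-recall
#' integration) are invariant to the monotone scaling.
#'
#' @param scores numeric vector of pair scores.
#' @param labels binary vector (1 = known association), same length.
#' @param threshold decision threshold on the (scaled) scores.
#' @param thresholdRule "fixed" uses \code{threshold}; "f1max" picks the
#'   scaled score cut maximizing F1.
#' @param scale min-max scale scores before thresholding (default TRUE).
#' @return named list: \code{counts} (TP, TN, FP, FN, threshold) and
#'   \code{metrics} (AUC, AUPR, F1, ACC, Recall, Precision, Specificity).
#' @examples
#' scoreMetrics(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
#' @export
scoreMetrics <- function(scores, labels, threshold = 0.5,
                         thresholdRule = c("fixed", "f1max"),
                         scale = TRUE) {
  thresholdRule <- match.arg(thresholdRule)
  if (length(scores) != length(labels))
    stop("scores and labels lengths differ")
  auc <- rocAuc(scores, labels)
  aupr <- prAuc(scores, labels)
  s <- if (scale) minmaxScale(scores) else scores
  if (thresholdRule == "f1max") {
    cand <- sort(unique(s))
    f1s <- vapply(cand, function(th) {
      tp <- sum(s >= th & labels == 1); fp <- sum(s >= th & labels == 0)
      fn <- sum(s < th & labels == 1)
      if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    }, 0)
    threshold <- cand[which.max(f1s)]
  }
  pred <- as.integer(s >= threshold)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(
    counts = c(TP = tp, TN = tn, FP = fp, FN = fn, threshold = threshold),
    metrics = c(AUC = auc, AUPR = aupr, F1 = f1,
                ACC = (tp + tn) / length(labels), Recall = recall,
                Precision = precision,
                Specificity = if (tn + fp == 0) 0 else tn / (tn + fp)))
}
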