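# Evaluation: confusion counts, the six report metrics, ROC and PR curves.

#' Confusion counts at a probability threshold
#'
#' A sample is predicted positive when its probability is greater than or
#' equal to `threshold` (ties count as positive).
#'
#' @param labels Binary 0/1 vector.
#' @param probabilities Numeric vector of the same length.
#' @param threshold Decision threshold (default 0.5).
#' @return One-row tibble with integer columns `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(labels, probabilities, threshold = 0.5) {
  if (length(labels) == 0L) abort("Cannot tally an empty input.")
  if (length(labels) != length(probabilities)) {
    abort("labels and probabilities differ in length")
  }
  if (!all(labels %in% c(0, 1))) abort("labels must be binary (0/1)")
  pred <- probabilities >= threshold
  tibble(
    tp = sum(pred & labels == 1), fp = sum(pred & labels == 0),
    fn = sum(!pred & labels == 1), tn = sum(!pred & labels == 0)
  )
}

#' Threshold metrics from confusion counts
#'
#' accuracy = (TP+TN)/n, precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2PR/(P+R). Zero-denominator cases return 0 rather than NaN so
#' tabulated reports never contain undefined cells.
#'
#' @param counts One-row tibble from [confusion_counts()].
#' @return One-row tibble: `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(counts) {
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  with(counts, {
    p <- safe_div(tp, tp + fp)
    r <- safe_div(tp, tp + fn)
    tibble(
      accuracy = safe_div(tp + tn, tp + fp + fn + tn),
      precision = p,
      recall = r,
      f1 = safe_div(2 * p * r, p + r)
    )
  })
}

#' Area under the ROC curve
#'
#' Mann–Whitney formulation: the probability that a uniformly chosen
#' positive outscores a uniformly chosen negative, with ties counted as
#' one half (midranks).
#'
#' @param labels Binary 0/1 vector containing both classes.
#' @param scores Numeric scores (any monotone scale).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  if (!all(labels %in% c(0, 1))) abort("labels must be binary (0/1)")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) abort("AUC undefined: both classes must be present")
  r <- rank(scores)  # average ranks on ties -> ties count 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Standard definitions: TPR = TP/(TP+FN), FPR = FP/(FP+TN), one point
#' per distinct score threshold (descending), anchored at (0,0) and
#' (1,1).
#'
#' @inheritParams roc_auc
#' @return Tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(labels, scores) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) abort("ROC undefined: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last <- cumsum(!duplicated(s, fromLast = TRUE))  # group ends of tied scores
  keep <- !duplicated(s)
  ends <- which(c(diff(s) != 0, TRUE))
  tp <- cumsum(y)[ends]
  fp <- cumsum(1 - y)[ends]
  tibble(
    threshold = c(Inf, s[ends]),
    fpr = c(0, fp / n0),
    tpr = c(0, tp / n1)
  )
}

#' Area under the precision–recall curve
#'
#' Step-wise rule: thresholds sweep the distinct scores in decreasing
#' order; the area adds precision at each step times the recall gained in
#' that step (no trapezoids). Tied scores move together.
#'
#' @inheritParams roc_auc
#' @return AUPR in (0, 1\].
#' @export
pr_auc <- function(labels, scores) {
  if (!all(labels %in% c(0, 1))) abort("labels must be binary (0/1)")
  pts <- pr_points(labels, scores)
  sum(diff(c(0, pts$recall)) * pts$precision)
}

#' Precision–recall curve points
#'
#' @inheritParams roc_auc
#' @return Tibble with columns `threshold`, `recall`, `precision`.
#' @export
pr_points <- function(labels, scores) {
  n1 <- sum(labels == 1)
  if (n1 == 0L) abort("PR curve undefined without positive samples")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  ends <- which(c(diff(s) != 0, TRUE))
  tp <- cumsum(y)[ends]
  n_pred <- ends
  tibble(
    threshold = s[ends],
    recall = tp / n1,
    precision = tp / n_pred
  )
}

#' Six-metric evaluation report
#'
#' @param labels Binary 0/1 vector.
#' @param probabilities Predicted probabilities.
#' @param threshold Threshold for the confusion-based metrics.
#' @return One-row tibble: `auc`, `accuracy`, `f1`, `precision`,
#'   `recall`, `aupr`.
#' @export
metric_report <- function(labels, probabilities, threshold = 0.5) {
  cls <- classification_metrics(confusion_counts(labels, probabilities,
                                                 threshold))
  tibble(
    auc = roc_auc(labels, probabilities),
    accuracy = cls$accuracy,
    f1 = cls$f1,
    precision = cls$precision,
    recall = cls$recall,
    aupr = pr_auc(labels, probabilities)
  )
}
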