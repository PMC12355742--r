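#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator: the probability that a random
#' positive scores above a random negative, counting ties as one half. This
#' equals the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric vector of predicted scores (any monotone scale).
#' @param labels Binary 0/1 vector, same length.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  check_scores_labels(scores, labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("auc is undefined when only one class is present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: sum over distinct score thresholds of
#' (recall increment) x (precision at that threshold), with no trapezoidal
#' interpolation. Ties in scores are handled by grouping, so the value does
#' not depend on the within-tie ordering. Under class imbalance this is the
#' primary comparison metric; a random ranker scores about the prevalence.
#'
#' @inheritParams auc
#' @return Average precision in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  check_scores_labels(scores, labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("auprc is undefined with no positive labels")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  grp_last <- cumsum(rle(s)$lengths)      # last index of each tie group
  tp <- cumsum(y)[grp_last]
  fp <- cumsum(1 - y)[grp_last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Recall, specificity and F1 at a probability threshold
#'
#' Predictions are positive when score > threshold. F1 is defined as 0 when
#' precision + recall is 0.
#'
#' @inheritParams auc
#' @param threshold Decision threshold in \[0, 1\] (default 0.5).
#' @return Named list with recall, specificity, f1 and the confusion counts.
#' @export
thresholded_metrics <- function(scores, labels, threshold = 0.5) {
  check_scores_labels(scores, labels)
  stopifnot(threshold >= 0, threshold <= 1)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  specificity <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (is.na(recall) || precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(recall = recall, specificity = specificity, f1 = f1,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' All evaluation metrics for one fold
#'
#' @inheritParams thresholded_metrics
#' @return A one-row data.frame: auc, auprc, recall, specificity, f1,
#'   threshold, n_pos, n_neg.
#' @export
metric_row <- function(scores, labels, threshold = 0.5) {
  tm <- thresholded_metrics(scores, labels, threshold)
  data.frame(auc = auc(scores, labels), auprc = auprc(scores, labels),
             recall = tm$recall, specificity = tm$specificity, f1 = tm$f1,
             threshold = threshold,
             n_pos = sum(labels == 1), n_neg = sum(labels == 0))
}

#' Aggregate per-fold metrics into mean (SD)
#'
#' Sample (n-1) standard deviation across folds; all folds must come from the
#' same experiment (identical threshold and evaluation-set composition).
#'
#' @param fold_rows data.frame of per-fold `metric_row` outputs (>= 2 rows).
#' @return List with `mean`, `sd` (named vectors over the five metrics),
#'   `n_folds`, `prevalence`.
#' @export
aggregate_metrics <- function(fold_rows) {
  if (nrow(fold_rows) < 2)
    stop("aggregation requires at least two folds")
  if (length(unique(fold_rows$threshold)) != 1 ||
      length(unique(fold_rows$n_pos)) != 1 ||
      length(unique(fold_rows$n_neg)) != 1)
    stop("folds do not belong to one experiment (mixed threshold or eval set)")
  cols <- c("auc", "auprc", "recall", "specificity", "f1")
  list(mean = vapply(cols, function(cc) mean(fold_rows[[cc]]), 0),
       sd = vapply(cols, function(cc) sd1(fold_rows[[cc]]), 0),
       n_folds = nrow(fold_rows),
       prevalence = fold_rows$n_pos[1] / (fold_rows$n_pos[1] + fold_rows$n_neg[1]))
}

check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0/1")
  invisible(TRUE)
}
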