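#' Single-fold classification metrics
#'
#' Accuracy, sensitivity (true-positive rate on the case class), specificity
#' (true-negative rate on the control class) and AUC. The AUC is the
#' rank-based (Mann-Whitney) statistic: the proportion of case-control pairs
#' the score orders correctly, with half credit for ties. A fold containing
#' only one class has an undefined AUC; it is returned as `NA` with a warning
#' and excluded from aggregation upstream.
#'
#' @param scores numeric case scores (higher = more case-like).
#' @param predictions 0/1 predicted classes.
#' @param labels 0/1 true classes.
#' @return list with `acc`, `sen`, `spe`, `auc`, and the confusion counts
#'   `tp`, `tn`, `fp`, `fn`.
#' @export
evaluateMetrics <- function(scores, predictions, labels) {
  stopifnot(length(scores) == length(labels),
            length(predictions) == length(labels))
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  tp <- sum(predictions == 1L & labels == 1L)
  tn <- sum(predictions == 0L & labels == 0L)
  fp <- sum(predictions == 1L & labels == 0L)
  fn <- sum(predictions == 0L & labels == 1L)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  acc <- (tp + tn) / length(labels)
  sen <- if (n1 > 0) tp / n1 else NA_real_
  spe <- if (n0 > 0) tn / n0 else NA_real_
  if (n1 == 0L || n0 == 0L) {
    warning("one-class fold: AUC undefined")
    auc <- NA_real_
  } else {
    r <- rank(scores)                    # average ranks give ties half credit
    auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(acc = acc, sen = sen, spe = spe, auc = auc,
       tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Stratified fold assignment
#'
#' Shuffles each class independently (seeded) and deals subjects round-robin
#' into `k` folds, so the class ratio is preserved within one subject per
#' fold, folds are disjoint and their union is the whole cohort.
#'
#' @param labels 0/1 class labels.
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @return integer vector of fold ids (1..k), one per subject.
#' @export
stratifiedFolds <- function(labels, k, seed = 1L) {
  labels <- as.integer(labels)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (any(table(labels) < k))
    stop("each class needs at least k subjects for stratified k-fold")
  folds <- integer(length(labels))
  withSeed(seed, {
    for (cl in unique(labels)) {
      ix <- which(labels == cl)
      ix <- ix[sample.int(length(ix))]
      folds[ix] <- rep_len(seq_len(k), length(ix))
    }
  })
  folds
}
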