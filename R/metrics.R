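# Evaluation metrics and the positive-unlabeled sampling protocol.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability
#' `(#\{pos > neg\} + 0.5 * #\{ties\}) / (n_pos * n_neg)` via average
#' ranks, which equals the trapezoidal area under the ROC curve with the
#' tie convention fixed at 0.5.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels.
#' @return Value in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) abort_shape("scores and labels differ in length")
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort_metric("ROC-AUC is undefined with a single class")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' The average-precision summation `sum_k (R_k - R_{k-1}) * P_k` over
#' descending score thresholds, with tied scores collapsed into one
#' threshold.
#'
#' @inheritParams roc_auc
#' @return Value in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) abort_shape("scores and labels differ in length")
  n_pos <- sum(y == 1)
  if (n_pos == 0) abort_metric("PR-AUC is undefined without positives")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- y[o]
  tp <- cumsum(y)
  k <- seq_along(y)
  # last index of each tied-score group = the threshold points
  last <- which(s != c(s[-1], NA) | k == length(s))
  prec <- tp[last] / k[last]
  rec <- tp[last] / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' F1 score of hard predictions
#'
#' `2PR / (P + R)`; defined as 0 when precision + recall is 0 (e.g., no
#' predicted positives).
#'
#' @param predicted Predicted binary labels.
#' @param actual True binary labels.
#' @return Value in `[0, 1]`.
#' @export
f1_score <- function(predicted, actual) {
  yhat <- as_binary_labels(predicted)
  y <- as_binary_labels(actual)
  if (length(yhat) != length(y)) abort_shape("label vectors differ in length")
  tp <- sum(yhat == 1 & y == 1)
  fp <- sum(yhat == 1 & y == 0)
  fn <- sum(yhat == 0 & y == 1)
  if (2 * tp + fp + fn == 0) {
    return(0)
  }
  2 * tp / (2 * tp + fp + fn)
}

#' Sample negatives from the unlabeled pool
#'
#' Uniform sampling without replacement of `ratio * n_pos` unlabeled
#' miRNAs; `ratio = "all"` returns the whole pool.
#'
#' @param unlabeled Character vector of unlabeled miRNA ids.
#' @param n_pos Number of positives.
#' @param ratio Positive multiple (e.g. 2, 10, 50) or `"all"`.
#' @param seed Integer seed.
#' @return Character vector of sampled negative ids.
#' @export
sample_negatives <- function(unlabeled, n_pos, ratio = "all", seed = 1L) {
  if (identical(ratio, "all")) {
    return(unlabeled)
  }
  check_scalar_number(ratio, "ratio", lower = 0, strict_lower = TRUE)
  need <- round(ratio * n_pos)
  if (need > length(unlabeled)) {
    abort_config(sprintf(
      "cannot sample %d negatives from an unlabeled pool of %d",
      need, length(unlabeled)
    ))
  }
  with_seed(seed, sample(unlabeled, need))
}

#' Stratified k-fold split
#'
#' Folds partition the data exactly; positives and negatives are shuffled
#' and dealt separately so every fold's positive fraction stays within one
#' sample of the global fraction.
#'
#' @param labels Binary labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of `k` lists with integer index vectors `train` and
#'   `test`.
#' @export
kfold_split <- function(labels, k = 5L, seed = 1L) {
  y <- as_binary_labels(labels)
  k <- check_count(k, "k", 2L)
  if (sum(y == 1) < k || sum(y == 0) < k) {
    abort_config(sprintf("need at least k = %d examples of each class", k))
  }
  assign_folds <- function(idx) {
    idx <- with_seed(seed + 31L * idx[1], sample(idx))
    split(idx, rep_len(seq_len(k), length(idx)))
  }
  pos_folds <- assign_folds(which(y == 1))
  neg_folds <- assign_folds(which(y == 0))
  lapply(seq_len(k), function(i) {
    test <- sort(c(pos_folds[[i]], neg_folds[[i]]))
    list(train = setdiff(seq_along(y), test), test = test)
  })
}
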