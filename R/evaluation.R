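#' Precision, recall and F-score from confusion counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F = 2PR/(P+R)`, reported on the
#' percentage scale. A zero denominator yields 0 by convention. Values are
#' unrounded; the print method displays two decimals (round half to even).
#'
#' @param counts Named list or vector with `TP`, `FP`, `FN` (and optionally
#'   `TN`).
#' @return List of class `prf` with `precision`, `recall`, `f` (percent).
#' @export
prf <- function(counts) {
  counts <- as.list(counts)
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  P <- if (TP + FP == 0) 0 else 100 * TP / (TP + FP)
  R <- if (TP + FN == 0) 0 else 100 * TP / (TP + FN)
  structure(list(precision = P, recall = R, f = f_score(P, R)), class = "prf")
}

#' @export
print.prf <- function(x, ...) {
  cat(sprintf("P = %.2f  R = %.2f  F = %.2f\n", x$precision, x$recall, x$f))
  invisible(x)
}

#' F-score as the harmonic mean of precision and recall
#'
#' @param precision,recall Values on the same scale (conventionally percent).
#' @return `2 * P * R / (P + R)`; 0 when both are 0.
#' @export
f_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Confusion counts of a binary prediction
#'
#' @param truth,pred Vectors of +1/-1 labels.
#' @return Named list `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  list(TP = sum(truth == 1 & pred == 1),
       FP = sum(truth == -1 & pred == 1),
       FN = sum(truth == 1 & pred == -1),
       TN = sum(truth == -1 & pred == -1))
}

#' Stratified k-fold split
#'
#' Partitions `1:n` into `k` disjoint folds whose per-class counts differ
#' from perfect proportionality by at most one instance. Deterministic under
#' `seed`.
#'
#' @param n Number of instances.
#' @param k Number of folds.
#' @param labels Class labels of length `n`.
#' @param seed Integer seed.
#' @return List of `k` integer index vectors.
#' @export
kfold_split <- function(n, k = 10L, labels, seed = 1L) {
  if (n < k) stopf("cannot make %d folds from %d instances", k, n)
  stopifnot(length(labels) == n)
  tab <- table(labels)
  if (any(tab < k))
    stopf("every class needs >= k = %d instances for stratification; got %s",
          k, paste(sprintf("%s:%d", names(tab), tab), collapse = ", "))
  folds <- vector("list", k)
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))        # shuffle, then deal round-robin
      for (i in seq_along(idx)) {
        f <- ((i - 1L) %% k) + 1L
        folds[[f]] <- c(folds[[f]], idx[i])
      }
    }
  })
  lapply(folds, sort)
}

#' ROC curve points
#'
#' One (FPR, TPR) point per distinct score threshold, thresholds descending,
#' anchored at (0,0) and (1,1); both coordinates are monotone non-decreasing.
#'
#' @param scores Numeric scores in \[0, 1\] (higher = more positive).
#' @param labels +1/-1 labels; both classes must be present.
#' @return Data frame with columns `fpr`, `tpr`, `threshold`.
#' @export
roc_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1); nneg <- sum(labels == -1)
  if (npos == 0 || nneg == 0)
    stopf("ROC requires both classes in `labels`")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / npos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == -1) / nneg,
                numeric(1))
  df <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                   threshold = c(Inf, thr))
  if (df$fpr[nrow(df)] != 1 || df$tpr[nrow(df)] != 1)
    df <- rbind(df, data.frame(fpr = 1, tpr = 1, threshold = -Inf))
  df
}

#' Trapezoid area under an ROC curve
#'
#' @param roc Output of [roc_points()].
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}
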