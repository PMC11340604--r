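# Binary-classification metric suite: AUC, balanced accuracy, F1, MCC,
# precision, recall, specificity.

#' Compute the full metric suite at a classification threshold
#'
#' Confusion counts use `score >= threshold` as the positive call.
#' MCC is `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined
#' as 0 when any factor of the denominator is 0. AUC is the rank statistic
#' (Mann-Whitney) with ties averaged; if only one class is present the
#' AUC is `NA` and a warning is raised, while the threshold metrics are
#' still computed.
#'
#' @param labels Binary truth (0/1 or logical).
#' @param scores Numeric scores, same length.
#' @param threshold Classification cut-off in \[0, 1\], default 0.5.
#' @return A `metrics_report` list: `auc`, `bacc`, `f1`, `mcc`,
#'   `precision`, `recall`, `specificity`, `threshold`, and the confusion
#'   counts `tp`, `fp`, `tn`, `fn`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  y <- as.integer(as.logical(labels))
  stopifnot(length(y) == length(scores))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  specificity <- if (tn + fp > 0L) tn / (tn + fp) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall /
    (precision + recall) else 0
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  auc <- if (length(unique(y)) < 2L) {
    warning("AUC undefined: only one class present", call. = FALSE)
    NA_real_
  } else {
    r <- rank(scores)
    np <- sum(y == 1L); nn <- sum(y == 0L)
    (sum(r[y == 1L]) - np * (np + 1) / 2) / (np * nn)
  }
  structure(list(auc = auc, bacc = (recall + specificity) / 2, f1 = f1,
                 mcc = mcc, precision = precision, recall = recall,
                 specificity = specificity, threshold = threshold,
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "AUC %.3f  bACC %.3f  F1 %.3f  MCC %.3f  P %.3f  R %.3f  Sp %.3f (thr %.3f)\n",
    x$auc, x$bacc, x$f1, x$mcc, x$precision, x$recall, x$specificity,
    x$threshold))
  invisible(x)
}

# Deterministic stratified fold assignment: within each class, a seeded
# shuffle followed by round-robin allocation to folds 1..k.
stratified_folds <- function(y, k, seed) {
  y <- as.integer(as.logical(y))
  fold <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    if (length(idx) < k) {
      stop("class count smaller than the number of folds", call. = FALSE)
    }
    idx <- with_rng(derive_seed(seed, cls + 10L), sample(idx))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Summarise a list of metrics_report objects as mean +/- sd per metric.
summarise_metrics <- function(reports) {
  keys <- c("auc", "bacc", "f1", "mcc", "precision", "recall",
            "specificity")
  m <- sapply(keys, function(k)
    vapply(reports, function(r) r[[k]], numeric(1L)))
  list(mean = colMeans(m), sd = apply(m, 2, stats::sd))
}
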