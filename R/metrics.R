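#' Binary confusion counts
#'
#' Counts with "hot" (label 1) as the positive class: TP are correctly
#' predicted hot proteins, TN correctly predicted cold, FP cold predicted
#' hot, FN hot predicted cold.
#'
#' @param pred,truth Equal-length binary (0/1) vectors.
#' @return List with integer fields `TP`, `TN`, `FP`, `FN` (class
#'   `confusion_counts`).
#' @export
confusion_counts <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  pred <- as.integer(pred); truth <- as.integer(truth)
  stopifnot(all(pred %in% 0:1), all(truth %in% 0:1))
  structure(list(TP = sum(pred == 1L & truth == 1L),
                 TN = sum(pred == 0L & truth == 0L),
                 FP = sum(pred == 1L & truth == 0L),
                 FN = sum(pred == 0L & truth == 1L)),
            class = "confusion_counts")
}

#' Classification accuracy
#'
#' (TP + TN) / (TP + TN + FP + FN).
#'
#' @param c A `confusion_counts`.
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(c) {
  n <- c$TP + c$TN + c$FP + c$FN
  if (n == 0L) stop("accuracy undefined on zero samples")
  (c$TP + c$TN) / n
}

#' Classification precision
#'
#' TP / (TP + FP): the proportion of proteins predicted hot that are truly
#' hot. When nothing is predicted positive the value is undefined; `NA` is
#' returned with a warning.
#'
#' @param c A `confusion_counts`.
#' @return Precision in \[0, 1\], or `NA` when undefined.
#' @export
precision <- function(c) {
  if (c$TP + c$FP == 0L) {
    warning("precision undefined: no positive predictions")
    return(NA_real_)
  }
  c$TP / (c$TP + c$FP)
}

#' ROC curve
#'
#' Sweeps the decision threshold over the unique scores (descending, with
#' +Inf prepended so the curve starts at (0, 0)) and accumulates the true
#' and false positive rates; the final point is (1, 1).
#'
#' @param scores Numeric scores, larger = more positive.
#' @param truth Binary labels (1 = positive); both classes must be present.
#' @return List of class `roc_curve` with `fpr`, `tpr`, `thresholds`.
#' @export
roc_curve <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  truth <- as.integer(truth)
  n_pos <- sum(truth == 1L); n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC requires both classes present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tp <- vapply(thr, function(t) sum(scores >= t & truth == 1L), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & truth == 0L), numeric(1))
  structure(list(fpr = fp / n_neg, tpr = tp / n_pos, thresholds = thr),
            class = "roc_curve")
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the fraction of positive-negative pairs
#' ranked correctly, with ties given half credit — so an uninformative
#' constant scorer yields exactly 0.5. Equals the trapezoidal area under
#' [roc_curve()].
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  truth <- as.integer(truth)
  n_pos <- sum(truth == 1L); n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("AUC requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Macro-averaged one-vs-rest ROC and AUC
#'
#' Computes a one-vs-rest ROC/AUC per class and averages the AUCs without
#' class weighting, so rare thermostability classes count as much as common
#' ones. The macro curve is the unweighted mean TPR interpolated on the
#' union of all per-class FPR grids.
#'
#' @param scores n x C matrix of class scores (columns in class order).
#' @param truth Length-n 0-based class indices; every class 0..C-1 must be
#'   present.
#' @return List with `per_class_auc`, `macro_auc`, `macro_curve` (list with
#'   `fpr`, `tpr`).
#' @export
macro_roc_auc <- function(scores, truth) {
  stopifnot(is.matrix(scores))
  C <- ncol(scores)
  truth <- as.integer(truth)
  missing <- setdiff(0:(C - 1L), unique(truth))
  if (length(missing))
    stop(sprintf("classes absent from truth: %s", paste(missing, collapse = ", ")))
  per_auc <- numeric(C)
  curves <- vector("list", C)
  for (k in seq_len(C)) {
    bin <- as.integer(truth == (k - 1L))
    per_auc[k] <- auc(scores[, k], bin)
    curves[[k]] <- roc_curve(scores[, k], bin)
  }
  grid <- sort(unique(unlist(lapply(curves, `[[`, "fpr"))))
  mean_tpr <- rowMeans(vapply(curves, function(cv) {
    stats::approx(cv$fpr, cv$tpr, xout = grid, ties = max, rule = 2)$y
  }, numeric(length(grid))))
  list(per_class_auc = per_auc, macro_auc = mean(per_auc),
       macro_curve = list(fpr = grid, tpr = mean_tpr))
}

#' Pearson correlation coefficient
#'
#' cov(x, y) / (sd(x) sd(y)); the normalization convention cancels in the
#' ratio.
#'
#' @param x,y Equal-length numeric vectors, n >= 2, nonzero variance.
#' @return Correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson correlation undefined for zero-variance input")
  stats::cor(x, y)
}

#' Spearman rank correlation coefficient
#'
#' Pearson correlation of average ranks (tie-safe); with all ranks distinct
#' this equals the classical 1 - 6 sum(d^2) / (n (n^2 - 1)).
#'
#' @inheritParams pearson
#' @return Correlation in \[-1, 1\].
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("Spearman correlation undefined for zero rank variance")
  stats::cor(rx, ry)
}

#' Coefficient of determination
#'
#' R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2): the proportion of
#' target variance explained by the predictions. Negative values are
#' possible (and returned) when the fit is worse than predicting the mean.
#'
#' @param y Observed values (non-constant, n >= 2).
#' @param yhat Predicted values.
#' @return R^2, at most 1, possibly negative.
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2L)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("R^2 undefined for constant y")
  1 - sum((y - yhat)^2) / ss_tot
}
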