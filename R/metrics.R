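#' Confusion matrix with nonmoving as the positive class
#'
#' Tallies binary labels with the convention used throughout: the positive
#' label (1) is "nonmoving" (the surrogate for potential unconsciousness),
#' the negative label (0) is "moving".
#'
#' @param truth,predicted equal-length vectors of 0/1 labels (or
#'   `"moving"`/`"nonmoving"` strings).
#' @return an object of class `confusion_matrix` with fields `TN`, `FP`,
#'   `FN`, `TP` and `N`.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as_label_code(truth)
  predicted <- as_label_code(predicted)
  if (length(truth) != length(predicted))
    stopf("truth and predicted lengths differ (%d vs %d)",
          length(truth), length(predicted))
  if (length(truth) == 0L) stopf("empty label vectors")
  new_confusion(TN = sum(truth == 0L & predicted == 0L),
                FP = sum(truth == 0L & predicted == 1L),
                FN = sum(truth == 1L & predicted == 0L),
                TP = sum(truth == 1L & predicted == 1L))
}

as_label_code <- function(x) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    bad <- !x %in% c("moving", "nonmoving")
    if (any(bad)) stopf("unknown label '%s'", x[which(bad)[1L]])
    return(ifelse(x == "nonmoving", 1L, 0L))
  }
  if (any(is.na(x)) || !all(x %in% c(0L, 1L)))
    stopf("labels must be 0 (moving) or 1 (nonmoving)")
  as.integer(x)
}

#' @rdname confusion_matrix
#' @param TN,FP,FN,TP non-negative integer counts.
#' @export
new_confusion <- function(TN, FP, FN, TP) {
  counts <- c(TN = TN, FP = FP, FN = FN, TP = TP)
  if (any(counts < 0) || any(counts != floor(counts)))
    stopf("confusion counts must be non-negative integers")
  N <- sum(counts)
  if (N == 0) stopf("confusion matrix is empty")
  structure(as.list(c(counts, N = N)), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> N=%d  (TN=%d FP=%d | FN=%d TP=%d)\n",
              x$N, x$TN, x$FP, x$FN, x$TP))
  invisible(x)
}

#' F-beta score
#'
#' Weighted harmonic combination of precision and recall,
#' `(1 + b^2) P R / (b^2 P + R)`; `beta = 1` gives the F1-score.
#'
#' @param cm a [confusion_matrix].
#' @param beta precision/recall trade-off parameter (default 1).
#' @return the F-beta score in `[0, 1]`.
#' @export
f_beta <- function(cm, beta = 1) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$TP + cm$FP == 0) stopf("precision undefined: TP + FP = 0")
  if (cm$TP + cm$FN == 0) stopf("recall undefined: TP + FN = 0")
  precision <- cm$TP / (cm$TP + cm$FP)
  recall <- cm$TP / (cm$TP + cm$FN)
  if (precision + recall == 0) return(0)
  (1 + beta^2) * precision * recall / (beta^2 * precision + recall)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(Pa - Pc) / (1 - Pc)` with `Pa` the observed
#' accuracy and `Pc` the agreement expected from the marginal rates.
#'
#' @param cm a [confusion_matrix].
#' @return kappa in `[-1, 1]`; errors when `Pc = 1` (single-class
#'   degenerate table).
#' @export
cohen_kappa <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  N <- cm$N
  pa <- (cm$TN + cm$TP) / N
  p1 <- (cm$TN + cm$FP) / N
  p2 <- (cm$TP + cm$FN) / N
  pc <- p1 * (cm$TN + cm$FN) / N + p2 * (cm$TP + cm$FP) / N
  if (pc == 1) stopf("kappa undefined: chance agreement Pc = 1")
  (pa - pc) / (1 - pc)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`: the correlation
#' between truth and prediction, robust to class imbalance; 1 for perfect,
#' 0 for random, -1 for perfectly wrong prediction.
#'
#' @param cm a [confusion_matrix].
#' @return MCC in `[-1, 1]`; errors when any marginal is zero.
#' @export
mcc <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- c(cm$TP + cm$FP, cm$TP + cm$FN, cm$TN + cm$FP, cm$TN + cm$FN)
  if (any(m == 0)) stopf("MCC undefined: a confusion-matrix marginal is zero")
  (cm$TP * cm$TN - cm$FP * cm$FN) / sqrt(prod(m))
}

#' Balanced error rate
#'
#' Mean of the two per-class error rates,
#' `(FP / (TN + FP) + FN / (TP + FN)) / 2`.
#'
#' @param cm a [confusion_matrix].
#' @return BER in `[0, 1]`; errors when a class is empty.
#' @export
ber <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$TN + cm$FP == 0 || cm$TP + cm$FN == 0)
    stopf("BER undefined: a true class is empty")
  (cm$FP / (cm$TN + cm$FP) + cm$FN / (cm$TP + cm$FN)) / 2
}

#' Area under the precision-recall curve
#'
#' Step integration over score thresholds (average precision): each
#' increment of recall contributes the precision at that threshold, with
#' the positive class = nonmoving and higher scores more positive. No
#' trapezoidal interpolation is applied.
#'
#' @param truth 0/1 labels (1 = nonmoving, the positive class).
#' @param scores continuous scores, higher = more positive.
#' @return the PR-AUC in `(0, 1]`.
#' @export
pr_auc <- function(truth, scores) {
  truth <- as_label_code(truth)
  if (length(truth) != length(scores)) stopf("truth and scores lengths differ")
  npos <- sum(truth == 1L)
  if (npos == 0L || npos == length(truth))
    stopf("PR-AUC undefined: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  truth <- truth[ord]; scores <- scores[ord]
  tp <- cumsum(truth == 1L)
  fp <- cumsum(truth == 0L)
  # evaluate at distinct thresholds (last index of each tied block)
  last <- which(diff(scores) != 0)
  idx <- c(last, length(scores))
  precision <- tp[idx] / (tp[idx] + fp[idx])
  recall <- tp[idx] / npos
  sum(diff(c(0, recall)) * precision)
}

#' Ratio of correctly predicted clips per study cell
#'
#' For each (posture, angle, movement) cell, the fraction of clips whose
#' predicted label matches the ground truth. Cells absent from the results
#' are reported as `NA`, not 0.
#'
#' @param results data frame with columns `posture`, `angle_deg`,
#'   `movement`, `truth`, `predicted` (0/1 or moving/nonmoving labels).
#' @return data frame with one row per (posture, angle_deg) and one column
#'   per movement class, values in `[0, 1]`.
#' @export
ratio_table <- function(results) {
  need <- c("posture", "angle_deg", "movement", "truth", "predicted")
  miss <- setdiff(need, names(results))
  if (length(miss)) stopf("results lack column(s): %s", paste(miss, collapse = ", "))
  results$correct <- as_label_code(results$truth) ==
    as_label_code(results$predicted)
  agg <- aggregate(correct ~ posture + angle_deg + movement, data = results,
                   FUN = mean)
  cells <- expand.grid(posture = unique(results$posture),
                       angle_deg = unique(results$angle_deg),
                       stringsAsFactors = FALSE)
  movements <- intersect(MOVEMENTS, unique(results$movement))
  out <- cells[order(cells$angle_deg, cells$posture), , drop = FALSE]
  for (mv in movements) {
    out[[mv]] <- vapply(seq_len(nrow(out)), function(i) {
      hit <- agg$posture == out$posture[i] & agg$angle_deg == out$angle_deg[i] &
        agg$movement == mv
      if (any(hit)) agg$correct[hit][1L] else NA_real_
    }, numeric(1L))
  }
  rownames(out) <- NULL
  out
}

#' Bundle the metric suite for one label set
#'
#' @param truth,predicted 0/1 labels.
#' @param scores optional continuous scores for PR-AUC.
#' @param beta F-score beta parameter.
#' @return an object of class `metrics_report`: confusion matrix plus
#'   `fbeta`, `kappa`, `mcc`, `ber` and (when scores are given) `auc_prc`.
#' @export
metrics_report <- function(truth, predicted, scores = NULL, beta = 1) {
  cm <- confusion_matrix(truth, predicted)
  rep <- list(cm = cm, beta = beta,
              fbeta = f_beta(cm, beta),
              kappa = cohen_kappa(cm),
              mcc = mcc(cm),
              ber = ber(cm),
              auc_prc = if (!is.null(scores)) pr_auc(truth, scores))
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  print(x$cm)
  cat(sprintf("  F%.3g %.3f | kappa %.3f | MCC %.3f | BER %.3f%s\n",
              x$beta, x$fbeta, x$kappa, x$mcc, x$ber,
              if (is.null(x$auc_prc)) ""
              else sprintf(" | AUC(PRC) %.3f", x$auc_prc)))
  invisible(x)
}
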