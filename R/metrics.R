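#' Binary classification metrics
#'
#' Confusion counts and the six standard QSAR performance metrics: balanced
#' accuracy `BA = (TPR + TNR) / 2`, mean misclassification error
#' `MMCE = (FP + FN) / n`, sensitivity (TPR), specificity (TNR), positive
#' predictive value `PPV = TP / (TP + FP)` (reported as `NA` when no positive
#' predictions were made — never 0 or 1), and the AUC computed from the rank
#' (Mann-Whitney) statistic when probabilities are supplied.
#'
#' @param pred binary predictions (0/1).
#' @param labels binary reference labels (0/1), 1 = DILI concern.
#' @param prob optional predicted probabilities of the positive class.
#' @return a list of class `PerformanceSummary`: `TP`, `FP`, `TN`, `FN`,
#'   `BA`, `MMCE`, `TPR`, `TNR`, `PPV`, `AUC` (`NA` without probabilities).
#' @examples
#' computeMetrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
computeMetrics <- function(pred, labels, prob = NULL) {
  pred <- as.integer(pred); labels <- as.integer(labels)
  if (length(pred) != length(labels)) stopf("pred and labels differ in length")
  if (!is.null(prob) && length(prob) != length(labels))
    stopf("prob and labels differ in length")
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  out <- list(
    TP = tp, FP = fp, TN = tn, FN = fn,
    BA = (tpr + tnr) / 2,
    MMCE = (fp + fn) / length(labels),
    TPR = tpr, TNR = tnr,
    PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    AUC = if (is.null(prob)) NA_real_ else rankAUC(prob, labels)
  )
  class(out) <- "PerformanceSummary"
  out
}

#' @export
print.PerformanceSummary <- function(x, ...) {
  cat(sprintf("BA %.3f | MMCE %.3f | TPR %.3f | TNR %.3f | PPV %s | AUC %s  (TP %d FP %d TN %d FN %d)\n",
              x$BA, x$MMCE, x$TPR, x$TNR,
              ifelse(is.na(x$PPV), "NA", sprintf("%.3f", x$PPV)),
              ifelse(is.na(x$AUC), "NA", sprintf("%.3f", x$AUC)),
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Keep models passing the BA/PPV selection rule
#'
#' A model enters the ensemble only when both its balanced accuracy and its
#' positive predictive value are *strictly* greater than the thresholds
#' (default 0.70 for both).
#'
#' @param summaries named list of `PerformanceSummary` objects (pooled
#'   out-of-fold metrics, one per model).
#' @param baMin,ppvMin strict lower bounds on BA and PPV.
#' @return character vector of the kept model keys.
#' @export
selectModels <- function(summaries, baMin = 0.70, ppvMin = 0.70) {
  keep <- vapply(summaries, function(s)
    isTRUE(s$BA > baMin) && isTRUE(s$PPV > ppvMin), logical(1))
  names(summaries)[keep]
}
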