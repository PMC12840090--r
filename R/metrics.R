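#' Confusion counts for binary predictions
#'
#' @param predicted,actual Vectors of 0/1 labels (1 = MDD, the positive class).
#' @return Named list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  predicted <- as.integer(predicted); actual <- as.integer(actual)
  stopifnot(all(predicted %in% 0:1), all(actual %in% 0:1))
  list(TP = sum(predicted == 1L & actual == 1L),
       TN = sum(predicted == 0L & actual == 0L),
       FP = sum(predicted == 1L & actual == 0L),
       FN = sum(predicted == 0L & actual == 1L))
}

#' Accuracy, sensitivity, specificity and F1 from confusion counts
#'
#' Computes Acc = (TP+TN)/(TP+TN+FP+FN), Sen = TP/(TP+FN),
#' Spe = TN/(TN+FP) and F1 = 2TP/(2TP+FP+FN), reported as percentages. A
#' metric whose denominator is zero is reported as 0 with a warning (this is
#' how degenerate band-ablation rows with no predicted or present positives
#' are tabulated).
#'
#' @param counts List with nonnegative integers `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   `f1`, each in `[0, 100]`.
#' @examples
#' compute_metrics(list(TP = 9, FN = 1, TN = 10, FP = 0))
#' @export
compute_metrics <- function(counts) {
  with(counts, {
    if (any(c(TP, TN, FP, FN) < 0)) stop("invalid input: negative counts", call. = FALSE)
    total <- TP + TN + FP + FN
    if (total == 0) stop("invalid input: empty confusion table", call. = FALSE)
    safe <- function(num, den, what) {
      if (den == 0) {
        warning(what, " undefined (zero denominator); reported as 0", call. = FALSE)
        return(0)
      }
      100 * num / den
    }
    c(accuracy = 100 * (TP + TN) / total,
      sensitivity = safe(TP, TP + FN, "sensitivity"),
      specificity = safe(TN, TN + FP, "specificity"),
      f1 = safe(2 * TP, 2 * TP + FP + FN, "F1"))
  })
}

#' Area under the ROC curve (percentage)
#'
#' Rank-based (Mann-Whitney) AUC with tie handling by rank averaging,
#' equivalent to the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric scores (larger = more MDD-like).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC as a percentage in `[0, 100]`.
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  100 * (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Mean +/- sd aggregation of a per-fold metrics matrix (folds x metrics).
aggregate_metrics <- function(per_fold) {
  data.frame(metric = colnames(per_fold),
             mean = colMeans(per_fold),
             sd = apply(per_fold, 2, stats::sd),
             row.names = NULL)
}
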