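# Ensemble-like classification: a long inference trial is segmented into
# short sub-trials, each classified independently by the network, and the
# sub-trial labels are fused by majority vote.

#' Segment a long trial into consecutive non-overlapping sub-trials
#'
#' @param trial `channels x samples` matrix.
#' @param window_seconds Sub-trial length in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @return List of `channels x n` matrices, `k = floor(N/n)` of them, starting
#'   at sample 1; a trailing remainder shorter than one window is discarded.
#' @export
segment_trial <- function(trial, window_seconds, sampling_rate) {
  stopifnot(is.matrix(trial))
  n <- as.integer(round(window_seconds * sampling_rate))
  N <- ncol(trial)
  if (N < n) {
    stop(sprintf("trial too short: %d samples < one %d-sample window", N, n),
         call. = FALSE)
  }
  k <- N %/% n
  lapply(seq_len(k), function(j) trial[, ((j - 1L) * n + 1L):(j * n), drop = FALSE])
}

#' Fuse sub-trial labels by majority vote
#'
#' Returns the label with the strictly larger count. A tie (possible only for
#' even `k`) is broken towards the class with the larger mean probability;
#' if those are also equal the healthy-control label 0 is returned, so a
#' screening decision never defaults to the disease label.
#'
#' @param labels Vector of 0/1 sub-trial labels.
#' @param probabilities Optional list (or `k x 2` matrix) of per-sub-trial
#'   class probability pairs, used only to break ties.
#' @return Single fused label, 0 or 1.
#' @examples
#' fuse_majority(c(1, 1, 0, 1, 0)) # 1
#' @export
fuse_majority <- function(labels, probabilities = NULL) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("invalid input: no sub-trial labels", call. = FALSE)
  stopifnot(all(labels %in% 0:1))
  n1 <- sum(labels == 1L); n0 <- length(labels) - n1
  if (n1 > n0) return(1L)
  if (n0 > n1) return(0L)
  if (!is.null(probabilities)) {
    if (is.list(probabilities)) probabilities <- do.call(rbind, probabilities)
    stopifnot(nrow(probabilities) == length(labels), ncol(probabilities) == 2L)
    m <- colMeans(probabilities)
    if (m[2] > m[1]) return(1L)
    if (m[1] > m[2]) return(0L)
  }
  0L
}

#' Classify a long trial with the ensemble-like voting classifier
#'
#' Segments the trial into non-overlapping sub-trials of the model's training
#' window, classifies each independently, and fuses the hard labels by
#' majority vote. The trial-level score (mean MDD probability across
#' sub-trials) is retained for ROC analysis.
#'
#' @param model A trained `mseegnet` model.
#' @param trial `channels x samples` matrix spanning at least one window.
#' @param window_seconds Sub-trial window; defaults to the model's training
#'   window.
#' @param sampling_rate Sampling rate; defaults to the model's configured rate.
#' @return An object of class `ensemble_prediction`: list with
#'   `subtrial_labels`, `subtrial_probabilities` (k x 2), `fused_label` and
#'   `trial_score`.
#' @export
predict_trial <- function(model, trial,
                          window_seconds = model$config$window_seconds,
                          sampling_rate = model$config$sampling_rate) {
  subs <- segment_trial(trial, window_seconds, sampling_rate)
  x <- array(unlist(subs), c(dim(subs[[1]]), length(subs)))
  probs <- predict(model, x, type = "prob")
  labels <- as.integer(probs[, 2] > probs[, 1])
  out <- list(subtrial_labels = labels,
              subtrial_probabilities = probs,
              fused_label = fuse_majority(labels, probs),
              trial_score = mean(probs[, 2]))
  class(out) <- "ensemble_prediction"
  out
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat(sprintf("ensemble prediction: fused label %d (%s), score %.3f, votes %s\n",
              x$fused_label, if (x$fused_label == 1L) "MDD" else "HC",
              x$trial_score, paste(x$subtrial_labels, collapse = "")))
  invisible(x)
}
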