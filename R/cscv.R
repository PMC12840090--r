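# Ten-fold cross-subject cross-validation of the full method: class
# balancing, subject-level stratified folds, sliding-window augmentation of
# the training subjects only, training per rotation, then evaluation of both
# the ensemble-like voting classifier (long trials) and the bare single-window
# classifier on the held-out test subjects.

subjects_table <- function(recordings) {
  data.frame(subject_id = vapply(recordings, `[[`, character(1), "subject_id"),
             label = vapply(recordings, `[[`, integer(1), "label"),
             stringsAsFactors = FALSE)
}

# Hard assertion that no subject leaks between the three roles, including
# through augmented trials.
assert_no_leakage <- function(train_ids, val_ids, test_ids) {
  if (length(intersect(train_ids, val_ids)) ||
      length(intersect(train_ids, test_ids)) ||
      length(intersect(val_ids, test_ids))) {
    stop("subject leakage detected across train/validation/test", call. = FALSE)
  }
  invisible(TRUE)
}

#' Run the full cross-subject cross-validation experiment
#'
#' For each of the `k` rotations: balance classes (seeded), split subjects
#' into train/validation/test folds, augment the training subjects with
#' sliding windows (validation and test are never augmented), train a fresh
#' model, then evaluate (a) the ensemble-like classifier on consecutive
#' `trial_seconds` trials of the test subjects and (b) the single-window
#' classifier on non-overlapping `window_seconds` trials. A subject-level
#' leakage guard is asserted on every rotation.
#'
#' @param recordings List of [eeg_recording()] objects (or a path to a
#'   dataset manifest).
#' @param model_config An [mseegnet_config()]; its channel split must match
#'   the recordings (after `montage`, if given).
#' @param control A [train_control()].
#' @param k Number of folds (default 10).
#' @param trial_seconds Length of an inference trial (default 10).
#' @param window_seconds Training window (default the model config's).
#' @param stride_seconds Augmentation stride (default 0.3).
#' @param montage Optional [channel_montage()] applied to every recording.
#' @param seed Master seed (balancing, folds, per-fold model init/shuffling).
#' @param keep_models Keep each fold's trained model (needed for band
#'   ablation / feature analysis afterwards).
#' @param verbose Print per-fold progress.
#' @return Object of class `cscv_result`: per-fold metric data frames
#'   `ensemble` and `single`, aggregate mean/sd tables, fold definitions,
#'   and (optionally) `models`.
#' @export
run_cscv <- function(recordings, model_config, control = train_control(),
                     k = 10L, trial_seconds = 10,
                     window_seconds = model_config$window_seconds,
                     stride_seconds = 0.3, montage = NULL, seed = 1L,
                     keep_models = FALSE, verbose = FALSE) {
  if (is.character(recordings)) recordings <- read_dataset(recordings)
  if (!is.null(montage)) recordings <- lapply(recordings, apply_montage, montage = montage)
  subj <- subjects_table(recordings)
  if (nrow(subj) < k) stop("dataset must have at least k subjects", call. = FALSE)
  balanced <- balance_classes(subj, seed = seed)
  recordings <- recordings[match(balanced$subject_id, subj$subject_id)]
  names(recordings) <- balanced$subject_id
  folds <- make_cscv_folds(balanced, k = k, seed = seed)

  ens_rows <- vector("list", k)
  sgl_rows <- vector("list", k)
  models <- if (keep_models) vector("list", k) else NULL
  test_sets <- vector("list", k)

  for (r in seq_len(k)) {
    fold <- folds[[r]]
    assert_no_leakage(fold$train, fold$val, fold$test)
    train_ts <- bind_trial_sets(lapply(recordings[fold$train],
                                       sliding_window_augment,
                                       window_seconds = window_seconds,
                                       stride_seconds = stride_seconds))
    val_ts <- bind_trial_sets(lapply(recordings[fold$val],
                                     epoch_nonoverlapping,
                                     window_seconds = window_seconds))
    assert_no_leakage(unique(train_ts$subject_id), unique(val_ts$subject_id),
                      fold$test)
    fold_ctrl <- control
    fold_ctrl$seed <- control$seed + r
    model <- mseegnet(model_config, seed = seed + 1000L * r)
    model <- train_mseegnet(model, train_ts$values, train_ts$label,
                            val_ts$values, val_ts$label, fold_ctrl)
    # (a) ensemble evaluation on long consecutive trials of the test subjects
    trials <- list(); tlabels <- integer(0); tsubj <- character(0)
    for (sid in fold$test) {
      rec <- recordings[[sid]]
      segs <- segment_trial(rec$values, trial_seconds, rec$sampling_rate)
      trials <- c(trials, segs)
      tlabels <- c(tlabels, rep(rec$label, length(segs)))
      tsubj <- c(tsubj, rep(sid, length(segs)))
    }
    preds <- integer(length(trials)); scores <- numeric(length(trials))
    for (i in seq_along(trials)) {
      ep <- predict_trial(model, trials[[i]], window_seconds)
      preds[i] <- ep$fused_label
      scores[i] <- ep$trial_score
    }
    m_ens <- suppressWarnings(compute_metrics(confusion_counts(preds, tlabels)))
    auc_ens <- if (length(unique(tlabels)) == 2L) compute_auc(scores, tlabels) else NA_real_
    ens_rows[[r]] <- data.frame(fold = r, t(m_ens), auc = auc_ens)
    # (b) single-window evaluation on non-overlapping short trials
    test_ts <- bind_trial_sets(lapply(recordings[fold$test],
                                      epoch_nonoverlapping,
                                      window_seconds = window_seconds))
    sp <- predict(model, test_ts$values, type = "prob")
    spred <- as.integer(sp[, 2] > sp[, 1])
    m_sgl <- suppressWarnings(compute_metrics(confusion_counts(spred, test_ts$label)))
    auc_sgl <- if (length(unique(test_ts$label)) == 2L) {
      compute_auc(sp[, 2], test_ts$label)
    } else NA_real_
    sgl_rows[[r]] <- data.frame(fold = r, t(m_sgl), auc = auc_sgl)
    test_sets[[r]] <- list(trials = trials, labels = tlabels, subjects = tsubj)
    if (keep_models) models[[r]] <- model
    if (verbose) {
      message(sprintf("fold %2d: ensemble acc %.1f%% | single acc %.1f%% (best epoch %d)",
                      r, m_ens["accuracy"], m_sgl["accuracy"], model$best_epoch))
    }
  }
  ensemble <- do.call(rbind, ens_rows)
  single <- do.call(rbind, sgl_rows)
  out <- list(ensemble = ensemble, single = single,
              ensemble_summary = aggregate_metrics(as.matrix(ensemble[, -1])),
              single_summary = aggregate_metrics(as.matrix(single[, -1])),
              folds = folds, models = models, test_sets = test_sets,
              subjects = balanced, seed = seed)
  class(out) <- "cscv_result"
  out
}

#' @export
print.cscv_result <- function(x, ...) {
  fmt <- function(s) paste(sprintf("%s %.2f +/- %.2f", s$metric, s$mean, s$sd),
                           collapse = ", ")
  cat("Cross-subject cross-validation (", nrow(x$ensemble), " folds)\n", sep = "")
  cat("  ensemble: ", fmt(x$ensemble_summary), "\n", sep = "")
  cat("  single:   ", fmt(x$single_summary), "\n", sep = "")
  invisible(x)
}

#' Index of the best fold of a cross-validation result
#'
#' @param result A `cscv_result`.
#' @param metric Metric column used for ranking (default accuracy).
#' @return Integer fold index (ties go to the earlier fold).
#' @export
best_fold <- function(result, metric = "accuracy") {
  which.max(result$ensemble[[metric]])
}
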