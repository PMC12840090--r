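# Recording container, readers, montage application, epoching, sliding-window
# augmentation, class balancing and subject-level stratified fold building.

#' Construct an EEG recording object
#'
#' @param subject_id Subject identifier string.
#' @param label 0 (healthy control) or 1 (MDD).
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_names Unique channel names, one per row of `values`.
#' @param values `channels x samples` numeric matrix, microvolts.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(subject_id, label, sampling_rate, channel_names, values) {
  stopifnot(is.matrix(values))
  if (length(channel_names) != nrow(values)) {
    stop("format error: 'channel_names' length must equal the matrix row count",
         call. = FALSE)
  }
  if (anyDuplicated(channel_names)) {
    stop("format error: 'channel_names' must be unique", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("format error: non-finite values in recording", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("format error: 'sampling_rate' must be positive", call. = FALSE)
  }
  label <- as.integer(label)
  stopifnot(label %in% 0:1)
  rec <- list(subject_id = as.character(subject_id), label = label,
              sampling_rate = sampling_rate,
              channel_names = as.character(channel_names), values = values)
  class(rec) <- "eeg_recording"
  rec
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording %s (label %d): %d channels x %d samples at %g Hz (%.1f s)\n",
              x$subject_id, x$label, nrow(x$values), ncol(x$values),
              x$sampling_rate, ncol(x$values) / x$sampling_rate))
  invisible(x)
}

#' Read one recording from disk
#'
#' Two formats are supported. `"manifest"` expects a JSON sidecar with fields
#' `subject_id`, `label`, `sampling_rate`, `channel_names` and `matrix_path`
#' (a headerless CSV, one row per channel, resolved relative to the sidecar).
#' `"edf"` reads a European Data Format file written by [write_edf()] or any
#' continuous EDF recorder; subject id is taken from the patient field and the
#' label from a `label=<0|1>` token in the recording field (default 0).
#'
#' @param path File path.
#' @param format `"manifest"` or `"edf"`.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("manifest", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("I/O error: file not found: ", path, call. = FALSE)
  if (format == "edf") return(read_edf(path))
  meta <- jsonlite::fromJSON(path)
  for (f in c("subject_id", "label", "sampling_rate", "channel_names", "matrix_path")) {
    if (is.null(meta[[f]])) {
      stop("format error: manifest missing field '", f, "'", call. = FALSE)
    }
  }
  mpath <- meta$matrix_path
  if (!file.exists(mpath)) mpath <- file.path(dirname(path), meta$matrix_path)
  values <- as.matrix(utils::read.csv(mpath, header = FALSE))
  dimnames(values) <- NULL
  eeg_recording(meta$subject_id, meta$label, meta$sampling_rate,
                meta$channel_names, values)
}

#' Write one recording as a manifest JSON + CSV matrix pair
#'
#' @param recording An [eeg_recording()].
#' @param path Path of the JSON sidecar to write; the matrix is written next
#'   to it as `<basename>.csv`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  csv_name <- paste0(sub("\\.json$", "", basename(path)), ".csv")
  utils::write.table(recording$values, file.path(dirname(path), csv_name),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  meta <- list(subject_id = recording$subject_id, label = recording$label,
               sampling_rate = recording$sampling_rate,
               channel_names = recording$channel_names,
               matrix_path = csv_name)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

## ---- montage ---------------------------------------------------------------

#' Define a channel montage
#'
#' A montage maps raw electrodes to derived model-input channels, each a
#' weighted combination of raw channels, tagged with the hemisphere it
#' belongs to. Derived channels are reordered right-hemisphere block first,
#' matching the network's hemispheric input convention.
#'
#' @param derived List of entries, each a list with `name`, `hemisphere`
#'   (`"right"` or `"left"`) and `weights` (named numeric vector over raw
#'   channel names).
#' @return Object of class `channel_montage`.
#' @export
channel_montage <- function(derived) {
  stopifnot(length(derived) >= 1L)
  hemi <- vapply(derived, function(d) d$hemisphere, character(1))
  stopifnot(all(hemi %in% c("right", "left")))
  if (!any(hemi == "right") || !any(hemi == "left")) {
    stop("montage error: at least one channel per hemisphere is required",
         call. = FALSE)
  }
  for (d in derived) {
    if (!all(is.finite(d$weights))) {
      stop("montage error: non-finite weights", call. = FALSE)
    }
  }
  m <- list(derived = c(derived[hemi == "right"], derived[hemi == "left"]),
            m_r = sum(hemi == "right"), m_l = sum(hemi == "left"))
  class(m) <- "channel_montage"
  m
}

#' Read a montage from a JSON file
#'
#' The JSON holds a list of objects with fields `name`, `hemisphere` and
#' `weights` (an object mapping raw channel names to weights). Example
#' montages, including the classic 10/20 channel-combination patterns, ship
#' under `system.file("extdata/montages", package = "mseegnet")`.
#'
#' @param path JSON file path.
#' @return A [channel_montage()].
#' @export
read_montage <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  channel_montage(lapply(raw, function(d) {
    list(name = d$name, hemisphere = d$hemisphere,
         weights = unlist(d$weights))
  }))
}

#' Apply a montage to a recording
#'
#' Each derived channel is the weighted sum of the referenced raw channels;
#' outputs are ordered right-hemisphere block then left-hemisphere block.
#'
#' @param recording An [eeg_recording()].
#' @param montage A [channel_montage()].
#' @return A new [eeg_recording()] with the derived channels.
#' @export
apply_montage <- function(recording, montage) {
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(montage, "channel_montage"))
  raw_names <- recording$channel_names
  out <- matrix(0, length(montage$derived), ncol(recording$values))
  for (i in seq_along(montage$derived)) {
    d <- montage$derived[[i]]
    missing <- setdiff(names(d$weights), raw_names)
    if (length(missing)) {
      stop("montage error: unknown raw channel(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    idx <- match(names(d$weights), raw_names)
    out[i, ] <- as.numeric(d$weights %*% recording$values[idx, , drop = FALSE])
  }
  eeg_recording(recording$subject_id, recording$label, recording$sampling_rate,
                vapply(montage$derived, function(d) d$name, character(1)), out)
}

## ---- epoching and augmentation ---------------------------------------------

new_trial_set <- function(values, subject_id, label, start_sample) {
  ts <- list(values = values, subject_id = subject_id, label = label,
             start_sample = start_sample)
  class(ts) <- "trial_set"
  ts
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("trial set: %d trials of %d channels x %d samples, %d subject(s)\n",
              dim(x$values)[3], dim(x$values)[1], dim(x$values)[2],
              length(unique(x$subject_id))))
  invisible(x)
}

# Shared windowing core: start samples (1-based) for given window/stride.
window_starts <- function(N, n, s) {
  if (N < n) stop("recording too short for one window", call. = FALSE)
  seq(1L, N - n + 1L, by = s)
}

#' Cut a recording into consecutive non-overlapping trials
#'
#' @param recording An [eeg_recording()].
#' @param window_seconds Trial length in seconds.
#' @return A `trial_set`: list with `values` (`channels x n x k` array),
#'   `subject_id`, `label` and `start_sample` vectors (one entry per trial).
#' @export
epoch_nonoverlapping <- function(recording, window_seconds) {
  n <- as.integer(round(window_seconds * recording$sampling_rate))
  sliding_window_augment(recording, window_seconds,
                         n / recording$sampling_rate)
}

#' Sliding-window augmentation of a recording
#'
#' Extracts windows starting at samples 1, 1+s, 1+2s, ... giving
#' `floor((N - n)/s) + 1` trials. With stride equal to the window this
#' reduces to non-overlapping epoching. A 0.3-s stride on 2-s windows
#' multiplies the trial count by roughly window/stride and is the training
#' augmentation used throughout; evaluation data is never augmented.
#'
#' @param recording An [eeg_recording()].
#' @param window_seconds Window length in seconds.
#' @param stride_seconds Stride in seconds; fractional sample counts are
#'   floored (with a warning).
#' @return A `trial_set` (see [epoch_nonoverlapping()]).
#' @export
sliding_window_augment <- function(recording, window_seconds, stride_seconds) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (stride_seconds <= 0) stop("stride must be positive", call. = FALSE)
  sr <- recording$sampling_rate
  n <- as.integer(round(window_seconds * sr))
  s_exact <- stride_seconds * sr
  s <- if (abs(s_exact - round(s_exact)) < 1e-6) {
    as.integer(round(s_exact))
  } else {
    as.integer(floor(s_exact))
  }
  if (s < 1L) stop("stride shorter than one sample", call. = FALSE)
  if (abs(s_exact - s) > 1e-6) {
    warning(sprintf("stride of %.3f samples floored to %d samples", s_exact, s),
            call. = FALSE)
  }
  starts <- window_starts(ncol(recording$values), n, s)
  k <- length(starts)
  vals <- array(0, c(nrow(recording$values), n, k))
  for (j in seq_len(k)) {
    vals[, , j] <- recording$values[, starts[j]:(starts[j] + n - 1L)]
  }
  new_trial_set(vals, rep(recording$subject_id, k),
                rep(recording$label, k), starts)
}

# Concatenate trial sets (same channel/sample geometry).
bind_trial_sets <- function(sets) {
  sets <- Filter(Negate(is.null), sets)
  stopifnot(length(sets) >= 1L)
  d <- dim(sets[[1]]$values)
  ks <- vapply(sets, function(s) dim(s$values)[3], integer(1))
  vals <- array(0, c(d[1], d[2], sum(ks)))
  at <- 0L
  for (s in sets) {
    k <- dim(s$values)[3]
    vals[, , at + seq_len(k)] <- s$values
    at <- at + k
  }
  new_trial_set(vals,
                unlist(lapply(sets, `[[`, "subject_id")),
                unlist(lapply(sets, `[[`, "label")),
                unlist(lapply(sets, `[[`, "start_sample")))
}

## ---- balancing and folds ---------------------------------------------------

#' Balance the two classes by downsampling the majority class
#'
#' The majority class is downsampled uniformly at random (seeded) to the
#' minority-class count, mirroring the matched-control design of balanced
#' clinical EEG studies; the minority class is untouched.
#'
#' @param subjects Data frame with columns `subject_id` and `label`.
#' @param seed Integer seed.
#' @return The balanced subject data frame (original row order preserved).
#' @export
balance_classes <- function(subjects, seed = 1L) {
  stopifnot(all(c("subject_id", "label") %in% names(subjects)))
  tab <- table(factor(subjects$label, levels = 0:1))
  if (any(tab == 0L)) stop("both classes must be present", call. = FALSE)
  n_min <- min(tab)
  maj <- names(tab)[which.max(tab)]
  if (tab[1] == tab[2]) return(subjects)
  maj_idx <- which(subjects$label == as.integer(maj))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  keep_maj <- sort(sample(maj_idx, n_min))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  keep <- sort(c(which(subjects$label != as.integer(maj)), keep_maj))
  subjects[keep, , drop = FALSE]
}

#' Build the rotating subject-level stratified cross-validation splits
#'
#' Subjects are shuffled within class (seeded) and dealt round-robin into `k`
#' folds, so per-fold class counts differ by at most one. Rotation `r` uses
#' fold `r` as the test set and fold `r + 1 (mod k)` as the validation set;
#' the remaining folds train. No subject appears in more than one of
#' train/validation/test within a rotation.
#'
#' @param subjects Data frame with `subject_id` and `label` columns.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the within-class shuffle.
#' @return List of `k` fold splits, each a list with `fold_assignments`
#'   (named fold index per subject, 0-based), `test_fold`, `val_fold`,
#'   `test`, `val`, `train` (subject-id character vectors).
#' @export
make_cscv_folds <- function(subjects, k = 10L, seed = 1L) {
  stopifnot(all(c("subject_id", "label") %in% names(subjects)))
  k <- as.integer(k)
  if (nrow(subjects) < k) {
    stop("fewer subjects than folds", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  assign_fold <- integer(nrow(subjects))
  at <- 0L
  for (cl in c(1L, 0L)) {
    idx <- which(subjects$label == cl)
    idx <- idx[sample.int(length(idx))]
    assign_fold[idx] <- (at + seq_along(idx) - 1L) %% k
    at <- at + length(idx)
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  names(assign_fold) <- subjects$subject_id
  lapply(seq_len(k) - 1L, function(r) {
    val <- (r + 1L) %% k
    list(fold_assignments = assign_fold,
         test_fold = r, val_fold = val,
         test = names(assign_fold)[assign_fold == r],
         val = names(assign_fold)[assign_fold == val],
         train = names(assign_fold)[assign_fold != r & assign_fold != val])
  })
}
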