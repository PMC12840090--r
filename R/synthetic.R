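# Synthetic EEG with subject structure and a controllable gamma-band class
# effect. Each channel is a sum over the five canonical bands of band-limited
# Gaussian noise (white noise passed through the same zero-phase Butterworth
# filters the interpretability analysis uses, then rescaled to unit RMS and
# multiplied by the band amplitude), plus broadband white noise. Class 1
# multiplies the gamma component's amplitude by `gamma_effect`. A per-subject
# lognormal amplitude factor is shared across that subject's channels and all
# its trials, giving the subject-specific structure that cross-subject
# validation must not be allowed to exploit.

#' Configuration of the synthetic EEG generator
#'
#' @param n_subjects_per_class Subjects per class.
#' @param duration_seconds Recording length (default 300 s, i.e. five-minute
#'   resting-state recordings).
#' @param sampling_rate Hz (default 250).
#' @param n_channels Total channels, split evenly right/left (default 32).
#' @param band_amplitudes Named per-band RMS amplitudes in microvolts for a
#'   healthy-control channel before subject/channel scaling.
#' @param gamma_effect Multiplicative gamma-amplitude factor for class 1
#'   (default 2: MDD gamma power is four times HC gamma power).
#' @param effect_band Band carrying the class effect (default `"gamma"`; any
#'   other band gives a negative control).
#' @param subject_sd Lognormal sigma of the per-subject amplitude factor.
#' @param channel_jitter Standard deviation of the per-channel multiplicative
#'   amplitude jitter around 1.
#' @param noise_amplitude Broadband white-noise RMS amplitude.
#' @param seed Master seed; every recording is reproducible from
#'   `(seed, subject_index, label)` alone.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects_per_class = 21L,
                             duration_seconds = 300,
                             sampling_rate = 250,
                             n_channels = 32L,
                             band_amplitudes = c(delta = 20, theta = 10,
                                                 alpha = 15, beta = 5, gamma = 2),
                             gamma_effect = 2,
                             effect_band = "gamma",
                             subject_sd = 0.2,
                             channel_jitter = 0.1,
                             noise_amplitude = 0.5,
                             seed = 1L) {
  stopifnot(n_subjects_per_class >= 1, duration_seconds > 0, sampling_rate >= 16,
            n_channels >= 2, n_channels %% 2 == 0,
            all(band_amplitudes >= 0), gamma_effect > 0,
            subject_sd >= 0, channel_jitter >= 0, noise_amplitude >= 0)
  stopifnot(effect_band %in% band_definitions()$name)
  stopifnot(all(sort(names(band_amplitudes)) == sort(band_definitions()$name)))
  cfg <- list(n_subjects_per_class = as.integer(n_subjects_per_class),
              duration_seconds = duration_seconds,
              sampling_rate = sampling_rate,
              n_channels = as.integer(n_channels),
              band_amplitudes = band_amplitudes,
              gamma_effect = gamma_effect,
              effect_band = effect_band,
              subject_sd = subject_sd,
              channel_jitter = channel_jitter,
              noise_amplitude = noise_amplitude,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

# Band-limited unit-RMS noise of length N; generated with edge padding so
# filter transients do not reach the kept segment.
band_limited_noise <- function(N, band, sampling_rate) {
  pad <- min(3L * as.integer(round(sampling_rate)), N)
  w <- stats::rnorm(N + 2L * pad)
  f <- bandpass(w, band, sampling_rate)
  f <- f[(pad + 1L):(pad + N)]
  s <- stats::sd(f)
  if (s < 1e-12) return(numeric(N))
  f / s
}

#' Generate one subject's synthetic recording
#'
#' @param config A [synthetic_config()].
#' @param subject_index 1-based subject index within its class.
#' @param label 0 (HC) or 1 (MDD).
#' @return An [eeg_recording()] with channel names `R01..` then `L01..`.
#' @export
generate_subject_recording <- function(config, subject_index, label) {
  stopifnot(inherits(config, "synthetic_config"))
  label <- as.integer(label)
  stopifnot(label %in% 0:1, subject_index >= 1)
  sr <- config$sampling_rate
  N <- as.integer(round(config$duration_seconds * sr))
  C <- config$n_channels
  half <- C %/% 2L

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed((config$seed * 10007L + subject_index * 211L + label) %% 2147483647L)
  subj_factor <- exp(stats::rnorm(1, 0, config$subject_sd))
  chan_factor <- pmax(1 + stats::rnorm(C, 0, config$channel_jitter), 0.1)

  amps <- config$band_amplitudes
  if (label == 1L) {
    amps[config$effect_band] <- amps[config$effect_band] * config$gamma_effect
  }
  values <- matrix(0, C, N)
  nonzero <- any(amps > 0) || config$noise_amplitude > 0
  if (nonzero && N > 0) {
    for (ch in seq_len(C)) {
      sig <- numeric(N)
      for (bn in band_definitions()$name) {
        if (amps[bn] > 0) {
          sig <- sig + amps[bn] * band_limited_noise(N, bn, sr)
        }
      }
      if (config$noise_amplitude > 0) {
        sig <- sig + config$noise_amplitude * stats::rnorm(N)
      }
      values[ch, ] <- subj_factor * chan_factor[ch] * sig
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  prefix <- if (label == 1L) "mdd" else "hc"
  eeg_recording(sprintf("%s%02d", prefix, subject_index), label, sr,
                c(sprintf("R%02d", seq_len(half)), sprintf("L%02d", seq_len(half))),
                values)
}

#' Generate a full synthetic cohort in memory
#'
#' @param config A [synthetic_config()].
#' @return List of `2 * n_subjects_per_class` [eeg_recording()] objects
#'   (controls first).
#' @export
generate_recordings <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  c(lapply(seq_len(config$n_subjects_per_class),
           function(i) generate_subject_recording(config, i, 0L)),
    lapply(seq_len(config$n_subjects_per_class),
           function(i) generate_subject_recording(config, i, 1L)))
}

#' Generate a synthetic dataset on disk
#'
#' Writes one manifest JSON + CSV matrix pair per subject plus a dataset
#' manifest (`manifest.json`) listing them, compatible with
#' [read_recording()].
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @param edf Also export each recording as EDF.
#' @return Path of the dataset manifest, invisibly.
#' @export
generate_dataset <- function(config, dir, edf = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- generate_recordings(config)
  entries <- lapply(recs, function(rec) {
    jpath <- file.path(dir, paste0(rec$subject_id, ".json"))
    write_recording(rec, jpath)
    if (edf) write_edf(rec, file.path(dir, paste0(rec$subject_id, ".edf")))
    list(path = basename(jpath), subject_id = rec$subject_id, label = rec$label)
  })
  manifest <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(entries, auto_unbox = TRUE, digits = NA), manifest)
  invisible(manifest)
}

#' Read every recording listed in a dataset manifest
#'
#' @param manifest Path to a `manifest.json` written by [generate_dataset()].
#' @return List of [eeg_recording()] objects.
#' @export
read_dataset <- function(manifest) {
  entries <- jsonlite::fromJSON(manifest, simplifyVector = FALSE)
  lapply(entries, function(e) {
    read_recording(file.path(dirname(manifest), e$path), "manifest")
  })
}
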