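# Minimal European Data Format (EDF) writer/reader for continuous multichannel
# recordings: 256-byte fixed header, 256 bytes per signal header, then data
# records of 16-bit little-endian integers with per-signal physical scaling.
# One data record per second (samples-per-record = sampling rate).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as an EDF file
#'
#' Subject id is stored in the patient-identification field and the class
#' label as a `label=<0|1>` token in the recording-identification field.
#' Samples are quantized to the 16-bit range spanned by each channel's
#' amplitude extrema.
#'
#' @param recording An [eeg_recording()] whose duration is an integer number
#'   of seconds and whose sampling rate is an integer.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  sr <- recording$sampling_rate
  if (abs(sr - round(sr)) > 1e-9) {
    stop("EDF export requires an integer sampling rate", call. = FALSE)
  }
  sr <- as.integer(round(sr))
  ns <- nrow(recording$values)
  N <- ncol(recording$values)
  if (N %% sr != 0L) {
    stop("EDF export requires a whole number of seconds", call. = FALSE)
  }
  n_rec <- N %/% sr
  phys_min <- apply(recording$values, 1, min)
  phys_max <- apply(recording$values, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, nchars = width, eos = NULL)
  wr("0", 8)                                   # version
  wr(recording$subject_id, 80)                 # patient id
  wr(sprintf("label=%d", recording$label), 80) # recording id
  wr("01.01.26", 8); wr("00.00.00", 8)         # start date/time
  wr(256 + ns * 256, 8)                        # header bytes
  wr("", 44)                                   # reserved
  wr(n_rec, 8)                                 # number of data records
  wr("1", 8)                                   # record duration, seconds
  wr(ns, 4)                                    # number of signals
  for (nm in recording$channel_names) wr(nm, 16)
  for (i in seq_len(ns)) wr("EEG", 80)         # transducer
  for (i in seq_len(ns)) wr("uV", 8)           # physical dimension
  for (i in seq_len(ns)) wr(sprintf("%.6g", phys_min[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", phys_max[i]), 8)
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)            # prefiltering
  for (i in seq_len(ns)) wr(sr, 8)             # samples per record
  for (i in seq_len(ns)) wr("", 32)            # reserved
  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * sr + 1L):(r * sr)
    for (i in seq_len(ns)) {
      dig <- round((recording$values[i, idx] - phys_min[i]) * gain[i] + dig_min)
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' @param path EDF file path.
#' @return An [eeg_recording()]. All signals must share one sampling rate.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                               # version
  subject_id <- rd(80)
  rec_id <- rd(80)
  rd(8); rd(8)                        # date/time
  rd(8)                               # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("format error: bad EDF signal count", call. = FALSE)
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L) {
    stop("format error: signals with differing sampling rates", call. = FALSE)
  }
  sr <- spr[1] / dur
  values <- matrix(0, ns, n_rec * spr[1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      values[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        (dig - dig_min[i]) * gain[i] + phys_min[i]
    }
  }
  label <- 0L
  m <- regmatches(rec_id, regexpr("label=[01]", rec_id))
  if (length(m)) label <- as.integer(sub("label=", "", m))
  eeg_recording(subject_id, label, sr, labels, values)
}
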