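# Interpretability: frequency-band ablation of a trained classifier and the
# correlation analysis between gamma-band energy and the learned features.

#' Band-ablation evaluation of a trained ensemble classifier
#'
#' Each labeled test trial is band-pass filtered into a single frequency band
#' and fed, unchanged otherwise, through the ensemble-like classifier; the
#' classification metrics per band show which rhythm carries the class
#' information. The classifier itself is untouched.
#'
#' @param model A trained `mseegnet` model.
#' @param trials List of `channels x samples` matrices (each spanning at
#'   least one training window).
#' @param labels 0/1 label per trial.
#' @param bands Character vector of band names (default all five).
#' @param sampling_rate Sampling rate; defaults to the model's.
#' @return Data frame, one row per band, columns `band`, `accuracy`,
#'   `sensitivity`, `specificity`, `auc`, `f1` (percentages).
#' @export
band_ablation <- function(model, trials, labels,
                          bands = band_definitions()$name,
                          sampling_rate = model$config$sampling_rate) {
  stopifnot(length(trials) == length(labels), length(trials) >= 1L)
  labels <- as.integer(labels)
  rows <- lapply(bands, function(bn) {
    preds <- integer(length(trials))
    scores <- numeric(length(trials))
    for (i in seq_along(trials)) {
      filt <- bandpass(trials[[i]], bn, sampling_rate)
      ep <- predict_trial(model, filt)
      preds[i] <- ep$fused_label
      scores[i] <- ep$trial_score
    }
    m <- suppressWarnings(compute_metrics(confusion_counts(preds, labels)))
    auc <- if (length(unique(labels)) == 2L) compute_auc(scores, labels) else NA_real_
    data.frame(band = bn, accuracy = m["accuracy"], sensitivity = m["sensitivity"],
               specificity = m["specificity"], auc = auc, f1 = m["f1"],
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Per-class Pearson correlation of learned features with gamma energy
#'
#' For each of the learned features, computes the Pearson correlation with
#' per-trial gamma energy separately within each class. A pair with zero
#' variance yields r = 0 with `degenerate = TRUE`.
#'
#' @param features `trials x features` matrix (e.g. from
#'   [extract_gap_features()]).
#' @param energies Per-trial gamma energies.
#' @param labels 0/1 class label per trial (both classes required, at least 3
#'   trials each).
#' @return Object of class `correlation_profile`: list with per-class `r`
#'   matrices (`feature`, `r`, `category`, `degenerate`) under `$HC` and
#'   `$MDD`.
#' @export
feature_band_correlation <- function(features, energies, labels) {
  stopifnot(is.matrix(features), nrow(features) == length(energies),
            length(energies) == length(labels))
  labels <- as.integer(labels)
  for (cl in 0:1) {
    if (sum(labels == cl) < 3L) {
      stop("need at least 3 trials in each class", call. = FALSE)
    }
  }
  one_class <- function(cl) {
    idx <- labels == cl
    e <- energies[idx]
    r <- vapply(seq_len(ncol(features)), function(j) {
      f <- features[idx, j]
      if (stats::sd(f) == 0 || stats::sd(e) == 0) return(NA_real_)
      stats::cor(f, e)
    }, numeric(1))
    degenerate <- is.na(r)
    r[degenerate] <- 0
    data.frame(feature = seq_len(ncol(features)), r = r,
               category = vapply(r, function(v) {
                 ct <- categorize_correlation(v)
                 paste(ct["strength"], ct["sign"])
               }, character(1)),
               degenerate = degenerate, stringsAsFactors = FALSE)
  }
  out <- list(HC = one_class(0L), MDD = one_class(1L))
  class(out) <- "correlation_profile"
  out
}

#' @export
print.correlation_profile <- function(x, ...) {
  for (cl in c("HC", "MDD")) {
    tab <- table(x[[cl]]$category)
    cat(cl, ": ", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Bar plot of a correlation profile
#'
#' One bar per learned feature, per class panel, colored by correlation
#' strength category.
#'
#' @param x A [feature_band_correlation()] result.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.correlation_profile <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  for (cl in c("HC", "MDD")) {
    r <- x[[cl]]$r
    cols <- ifelse(abs(r) >= 0.7, "firebrick",
                   ifelse(abs(r) >= 0.3, "steelblue", "grey70"))
    graphics::barplot(r, col = cols, border = NA, ylim = c(-1, 1),
                      main = paste(cl, "features vs gamma energy"),
                      ylab = "Pearson r", ...)
    graphics::abline(h = c(-0.7, -0.3, 0, 0.3, 0.7), lty = 3, col = "grey50")
  }
  invisible(x)
}

#' Categorize a correlation coefficient by strength and sign
#'
#' Strength thresholds are applied to the magnitude: strong when
#' `|r| >= 0.7`, moderate when `0.3 <= |r| < 0.7`, weak when `|r| < 0.3`;
#' the sign is reported separately.
#'
#' @param r Correlation coefficient in `[-1, 1]`.
#' @return Named character vector with `strength` and `sign`.
#' @examples
#' categorize_correlation(0.7)  # strong positive
#' categorize_correlation(-0.5) # moderate negative
#' @export
categorize_correlation <- function(r) {
  if (!is.finite(r) || abs(r) > 1) {
    stop("invalid input: |r| must be <= 1", call. = FALSE)
  }
  strength <- if (abs(r) >= 0.7) "strong" else if (abs(r) >= 0.3) "moderate" else "weak"
  sign <- if (r > 0) "positive" else if (r < 0) "negative" else "zero"
  c(strength = strength, sign = sign)
}

#' Marker features from correlation profiles across folds
#'
#' A feature is a marker when its correlation with gamma energy has the
#' opposite sign between the two classes in every fold (the clinically
#' interesting signature: e.g. negative in healthy controls and positive in
#' MDD throughout). For the markers, per-class mean and standard deviation of
#' the feature activations are reported together with a flag telling whether
#' the two `[mean - sd, mean + sd]` intervals overlap.
#'
#' @param profiles List of [feature_band_correlation()] results, one per fold
#'   (at least 2 folds).
#' @param features `trials x features` activation matrix pooled over folds.
#' @param labels 0/1 label per pooled trial.
#' @return List with `markers` (integer feature indices) and `stats`
#'   (data frame: feature, class means/sds, `overlap` flag).
#' @export
marker_feature_report <- function(profiles, features, labels) {
  stopifnot(length(profiles) >= 2L)
  labels <- as.integer(labels)
  nf <- nrow(profiles[[1]]$HC)
  opposite <- rep(TRUE, nf)
  for (p in profiles) {
    s_hc <- sign(p$HC$r)
    s_mdd <- sign(p$MDD$r)
    opposite <- opposite & (s_hc * s_mdd < 0)
  }
  markers <- which(opposite)
  stats_df <- NULL
  if (length(markers) && !is.null(features)) {
    stats_df <- do.call(rbind, lapply(markers, function(j) {
      f0 <- features[labels == 0L, j]; f1 <- features[labels == 1L, j]
      m0 <- mean(f0); s0 <- stats::sd(f0)
      m1 <- mean(f1); s1 <- stats::sd(f1)
      data.frame(feature = j, hc_mean = m0, hc_sd = s0,
                 mdd_mean = m1, mdd_sd = s1,
                 overlap = (m0 - s0) <= (m1 + s1) && (m1 - s1) <= (m0 + s0))
    }))
  }
  list(markers = markers, stats = stats_df)
}
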