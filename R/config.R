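#' Derive the multiscale temporal kernel lengths from the sampling rate
#'
#' The three parallel depthwise temporal convolutions of the multiscale block
#' use kernels spanning one half, one quarter and one eighth of a second, so
#' their lengths in samples are `floor(SR/2)`, `floor(SR/4)` and `floor(SR/8)`.
#'
#' @param sampling_rate Sampling rate in Hz (must be at least 16 so that the
#'   shortest kernel has at least two taps).
#' @return Integer vector `c(S1, S2, S3)` of kernel lengths in samples.
#' @examples
#' derive_scales(250) # 125 62 31
#' @export
derive_scales <- function(sampling_rate) {
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("invalid config: 'sampling_rate' must be a positive number", call. = FALSE)
  }
  if (sampling_rate < 16) {
    stop("invalid config: 'sampling_rate' must be >= 16 Hz", call. = FALSE)
  }
  s <- as.integer(floor(sampling_rate / c(2, 4, 8)))
  names(s) <- c("S1", "S2", "S3")
  s
}

#' Architecture configuration for the multiscale EEG network
#'
#' Collects every architecture hyperparameter of the network: the hemispheric
#' channel split, trial geometry, spatial filter count, depthwise depth
#' multiplier, the three temporal scales, separable-block widths, pooling and
#' the normalization/activation options explored in the ablation axes.
#'
#' @param m_r,m_l Number of right- and left-hemisphere input channels.
#' @param sampling_rate Sampling rate in Hz.
#' @param window_seconds Training-trial length in seconds (default 2).
#' @param F1 Number of spatial filters (default 8).
#' @param D Depth multiplier of the depthwise temporal convolutions (default 2).
#' @param scales Ordered temporal kernel lengths in samples; defaults to
#'   [derive_scales()] of the sampling rate.
#' @param F2 Output channels of the second separable block and hence the
#'   learned-feature width (default 48).
#' @param F3 Channels of the first pointwise layer (default 96).
#' @param pool_window,pool_stride Mid temporal pooling geometry (default 4/4).
#' @param activation One of `"relu"`, `"gelu"`, `"leaky_relu"`, `"swish"`,
#'   `"tanh"`, `"clipped_relu"`.
#' @param spatial_norm,temporal_norm Normalization used in the spatial block
#'   and in the temporal blocks: `"group"`, `"batch"` or `"layer"`.
#' @param gn_groups Group count for group normalization; must divide `F1`.
#' @param norm_after_activation If `TRUE` (default) layers compose as
#'   convolution, activation, normalization; `FALSE` gives the conventional
#'   convolution, normalization, activation order.
#' @param pooling_kind Length-2 character vector for the mid and global
#'   pooling, each `"average"` or `"max"`.
#' @param n_classes Number of classes (fixed at 2).
#' @return An object of class `mseegnet_config`.
#' @examples
#' cfg <- mseegnet_config(m_r = 16, m_l = 16, sampling_rate = 250)
#' cfg$n # 500
#' @export
mseegnet_config <- function(m_r = 16L, m_l = 16L, sampling_rate = 250,
                            window_seconds = 2, F1 = 8L, D = 2L,
                            scales = NULL, F2 = 48L, F3 = 96L,
                            pool_window = 4L, pool_stride = 4L,
                            activation = c("relu", "gelu", "leaky_relu",
                                           "swish", "tanh", "clipped_relu"),
                            spatial_norm = c("group", "batch", "layer"),
                            temporal_norm = c("batch", "group", "layer"),
                            gn_groups = 1L, norm_after_activation = TRUE,
                            pooling_kind = c("average", "average"),
                            n_classes = 2L) {
  activation <- match.arg(activation)
  spatial_norm <- match.arg(spatial_norm)
  temporal_norm <- match.arg(temporal_norm)
  stopifnot(length(pooling_kind) == 2L)
  pooling_kind <- vapply(pooling_kind,
                         function(p) match.arg(p, c("average", "max")),
                         character(1), USE.NAMES = FALSE)
  if (is.null(scales)) scales <- derive_scales(sampling_rate)
  cfg <- list(
    m_r = as.integer(m_r), m_l = as.integer(m_l),
    sampling_rate = sampling_rate,
    window_seconds = window_seconds,
    n = as.integer(round(sampling_rate * window_seconds)),
    F1 = as.integer(F1), D = as.integer(D),
    scales = as.integer(scales),
    F2 = as.integer(F2), F3 = as.integer(F3),
    pool_window = as.integer(pool_window),
    pool_stride = as.integer(pool_stride),
    activation = activation,
    spatial_norm = spatial_norm,
    temporal_norm = temporal_norm,
    gn_groups = as.integer(gn_groups),
    norm_after_activation = isTRUE(norm_after_activation),
    pooling_kind = pooling_kind,
    n_classes = as.integer(n_classes)
  )
  class(cfg) <- "mseegnet_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  fail <- function(msg) stop("invalid config: ", msg, call. = FALSE)
  if (cfg$m_r < 1L || cfg$m_l < 1L) fail("m_r and m_l must each be >= 1")
  if (cfg$sampling_rate <= 0) fail("sampling_rate must be positive")
  n_exact <- cfg$sampling_rate * cfg$window_seconds
  if (abs(n_exact - round(n_exact)) > 1e-8) {
    fail("sampling_rate * window_seconds must be an integer sample count")
  }
  if (cfg$n < 1L) fail("trial length n must be >= 1 sample")
  if (length(cfg$scales) != 3L) fail("exactly three temporal scales are required")
  if (any(cfg$scales <= 0L)) fail("temporal scales must be positive")
  if (is.unsorted(rev(cfg$scales))) fail("temporal scales must be non-increasing")
  if (any(cfg$scales > cfg$n)) fail("every temporal scale must be <= n")
  if (cfg$F1 < 1L || cfg$D < 1L || cfg$F2 < 1L || cfg$F3 < 1L) {
    fail("F1, D, F2 and F3 must be positive")
  }
  if (cfg$gn_groups < 1L || cfg$F1 %% cfg$gn_groups != 0L) {
    fail("gn_groups must be a positive divisor of F1")
  }
  if (cfg$pool_window < 1L || cfg$pool_stride < 1L) fail("pooling geometry must be positive")
  if (cfg$n < cfg$pool_window) fail("n must be at least pool_window")
  if (cfg$n_classes != 2L) fail("only binary classification is supported")
  invisible(cfg)
}

#' @export
print.mseegnet_config <- function(x, ...) {
  cat("Multiscale EEG network configuration\n")
  cat(sprintf("  channels: %d right + %d left, trial %g s at %g Hz (n = %d)\n",
              x$m_r, x$m_l, x$window_seconds, x$sampling_rate, x$n))
  cat(sprintf("  F1 = %d, D = %d, scales = %s, F2 = %d, F3 = %d\n",
              x$F1, x$D, paste(x$scales, collapse = "/"), x$F2, x$F3))
  cat(sprintf("  activation %s; spatial norm %s (%d group%s), temporal norm %s\n",
              x$activation, x$spatial_norm, x$gn_groups,
              if (x$gn_groups == 1L) "" else "s", x$temporal_norm))
  cat(sprintf("  pooling %s (mid %dx%d) / %s (global); order conv -> %s\n",
              x$pooling_kind[1], x$pool_window, x$pool_stride, x$pooling_kind[2],
              if (x$norm_after_activation) "activation -> norm" else "norm -> activation"))
  invisible(x)
}
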