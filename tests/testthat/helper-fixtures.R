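# Shared fixtures: a desk-scale architecture (32 Hz, 4 channels, 1-s windows)
# used wherever the full-size geometry is not itself under test, plus a cached
# trained instance for tests that need a fitted classifier.

tiny_config <- function(...) {
  mseegnet_config(m_r = 2, m_l = 2, sampling_rate = 32, window_seconds = 1, ...)
}

# Linearly separable trials for the tiny geometry: class 1 carries a strong
# high-frequency tone on every channel, class 0 is pure noise.
tiny_trials <- function(n_per_class, seed = 1, sep = 3) {
  set.seed(seed)
  n <- 32L
  k <- 2L * n_per_class
  x <- array(rnorm(4 * n * k), c(4, n, k))
  y <- rep(0:1, each = n_per_class)
  tone <- sin(2 * pi * 12 * seq_len(n) / 32)
  for (j in which(y == 1L)) {
    x[, , j] <- x[, , j] + sep * matrix(tone, 4, n, byrow = TRUE)
  }
  list(x = x, y = y)
}

.fixture_env <- new.env(parent = emptyenv())

# A small model trained once per test run on separable tiny trials.
trained_tiny_model <- function() {
  if (is.null(.fixture_env$model)) {
    tr <- tiny_trials(30, seed = 11)
    va <- tiny_trials(8, seed = 12)
    ctrl <- train_control(max_epochs = 8, batch_size = 16, seed = 5)
    model <- mseegnet(tiny_config(), seed = 5)
    .fixture_env$model <- train_mseegnet(model, tr$x, tr$y, va$x, va$y, ctrl)
  }
  .fixture_env$model
}

# A miniature synthetic cohort shared by pipeline-level tests. The sampling
# rate stays above 67 Hz so the gamma band survives the Nyquist clipping.
tiny_cohort <- function(n_per_class = 5, duration = 12, seed = 99, ...) {
  key <- paste(c("cohort", n_per_class, duration, seed, ...), collapse = "_")
  if (is.null(.fixture_env[[key]])) {
    cfg <- synthetic_config(n_subjects_per_class = n_per_class,
                            duration_seconds = duration, sampling_rate = 128,
                            n_channels = 4, seed = seed, ...)
    .fixture_env[[key]] <- generate_recordings(cfg)
  }
  .fixture_env[[key]]
}
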