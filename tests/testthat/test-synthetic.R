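# The synthetic EEG generator: determinism, degenerate configs, the
# gamma-band class effect and the spectral contract.

test_that("generation is fully reproducible from the seed", {
  cfg <- synthetic_config(n_subjects_per_class = 2, duration_seconds = 4,
                          sampling_rate = 128, n_channels = 4, seed = 7)
  a <- generate_subject_recording(cfg, 1, 1L)
  b <- generate_subject_recording(cfg, 1, 1L)
  expect_identical(a, b)
  c2 <- generate_subject_recording(cfg, 2, 1L)
  expect_false(identical(a$values, c2$values))
  # the generator must not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_subject_recording(cfg, 1, 0L))
  expect_identical(rnorm(1), before)
})

test_that("all-zero amplitudes give an all-zero recording", {
  cfg <- synthetic_config(n_subjects_per_class = 1, duration_seconds = 2,
                          sampling_rate = 128, n_channels = 4,
                          band_amplitudes = c(delta = 0, theta = 0, alpha = 0,
                                              beta = 0, gamma = 0),
                          noise_amplitude = 0, seed = 1)
  rec <- generate_subject_recording(cfg, 1, 0L)
  expect_true(all(rec$values == 0))
})

test_that("recordings carry the configured geometry and metadata", {
  cfg <- synthetic_config(n_subjects_per_class = 3, duration_seconds = 5,
                          sampling_rate = 128, n_channels = 6, seed = 2)
  recs <- generate_recordings(cfg)
  expect_length(recs, 6)
  expect_equal(sum(vapply(recs, `[[`, integer(1), "label") == 0L), 3)
  r <- recs[[1]]
  expect_equal(dim(r$values), c(6L, 5L * 128L))
  expect_equal(r$channel_names, c("R01", "R02", "R03", "L01", "L02", "L03"))
})

test_that("the gamma effect scales class-1 gamma energy quadratically", {
  recs <- tiny_cohort(n_per_class = 10, duration = 8, seed = 61)
  e <- vapply(recs, function(r) gamma_energy(r$values, r$sampling_rate),
              numeric(1))
  labels <- vapply(recs, `[[`, integer(1), "label")
  ratio <- mean(e[labels == 1]) / mean(e[labels == 0])
  expect_equal(ratio, 4, tolerance = 0.2 * 4)
})

test_that("without a gamma effect the classes are spectrally exchangeable", {
  recs <- tiny_cohort(n_per_class = 10, duration = 8, seed = 62,
                      gamma_effect = 1)
  e <- vapply(recs, function(r) gamma_energy(r$values, r$sampling_rate),
              numeric(1))
  labels <- vapply(recs, `[[`, integer(1), "label")
  p <- stats::t.test(log(e[labels == 1]), log(e[labels == 0]))$p.value
  expect_gt(p, 0.01)
})

test_that("per-band power ordering follows the configured amplitudes", {
  cfg <- synthetic_config(n_subjects_per_class = 1, duration_seconds = 20,
                          sampling_rate = 250, n_channels = 2,
                          subject_sd = 0, channel_jitter = 0,
                          noise_amplitude = 0, seed = 63)
  rec <- generate_subject_recording(cfg, 1, 0L)
  bandpow <- vapply(band_definitions()$name, function(bn) {
    gamma_energy(rec$values, rec$sampling_rate, band = bn)
  }, numeric(1))
  expect_equal(order(bandpow, decreasing = TRUE),
               order(cfg$band_amplitudes^2, decreasing = TRUE))
})

test_that("datasets round-trip through the on-disk manifest", {
  cfg <- synthetic_config(n_subjects_per_class = 2, duration_seconds = 2,
                          sampling_rate = 128, n_channels = 4, seed = 8)
  dir <- withr::local_tempdir()
  manifest <- generate_dataset(cfg, dir)
  expect_true(file.exists(manifest))
  recs <- read_dataset(manifest)
  expect_length(recs, 4)
  direct <- generate_recordings(cfg)
  expect_equal(recs[[1]]$values, direct[[1]]$values, tolerance = 1e-10)
  expect_identical(vapply(recs, `[[`, character(1), "subject_id"),
                   vapply(direct, `[[`, character(1), "subject_id"))
  # byte-identical regeneration under the same seed
  dir2 <- withr::local_tempdir()
  generate_dataset(cfg, dir2)
  f1 <- file.path(dir, "hc01.csv"); f2 <- file.path(dir2, "hc01.csv")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("EDF export of synthetic recordings re-reads within quantization", {
  cfg <- synthetic_config(n_subjects_per_class = 1, duration_seconds = 2,
                          sampling_rate = 128, n_channels = 4, seed = 9)
  dir <- withr::local_tempdir()
  generate_dataset(cfg, dir, edf = TRUE)
  rec <- generate_subject_recording(cfg, 1, 0L)
  back <- read_edf(file.path(dir, "hc01.edf"))
  expect_equal(back$subject_id, rec$subject_id)
  expect_equal(back$label, rec$label)
  span <- apply(rec$values, 1, function(v) diff(range(v)))
  expect_lt(max(abs(back$values - rec$values) / span), 1 / 65000)
})
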