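# Band-pass filtering, gamma energy, correlation profiles and marker features.

tone <- function(freq, sr, seconds = 4, amp = 1) {
  amp * sin(2 * pi * freq * seq_len(seconds * sr) / sr)
}

# amplitude ratio measured on the central 80% to stay clear of edge effects
amp_ratio <- function(filtered, original) {
  n <- length(original)
  core <- seq(floor(n * 0.1), ceiling(n * 0.9))
  sqrt(mean(filtered[core]^2) / mean(original[core]^2))
}

test_that("band definitions cover the canonical rhythms", {
  b <- band_definitions()
  expect_equal(b$name, c("delta", "theta", "alpha", "beta", "gamma"))
  expect_equal(b$low, c(0.5, 4, 8, 13, 30))
  expect_equal(b$high, c(4, 8, 13, 30, 100))
})

test_that("the gamma filter passes in-band tones and rejects out-of-band ones", {
  sr <- 250
  x50 <- tone(50, sr)
  expect_gte(amp_ratio(bandpass(x50, "gamma", sr), x50), 0.9)
  expect_lte(amp_ratio(bandpass(x50, "alpha", sr), x50), 0.1)
  x10 <- tone(10, sr)
  expect_gte(amp_ratio(bandpass(x10, "alpha", sr), x10), 0.9)
  expect_lte(amp_ratio(bandpass(x10, "gamma", sr), x10), 0.1)
  # DC is outside every band
  dc <- rep(1, 1000)
  for (bn in band_definitions()$name) {
    expect_lte(max(abs(bandpass(dc, bn, sr)[100:900])), 1e-3)
  }
  expect_error(bandpass(x50, list(low = 130, high = 140), sr), "Nyquist|invalid")
})

test_that("filtering is zero-phase and shape preserving", {
  sr <- 250
  x <- tone(45, sr) + 0.1 * rnorm(1000)
  f <- bandpass(x, "gamma", sr)
  expect_length(f, length(x))
  cc <- stats::ccf(f[100:900], tone(45, sr)[100:900], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(abs(cc$acf))], 0)
  # matrices filter per channel
  xm <- rbind(x, tone(10, sr))
  fm <- bandpass(xm, "gamma", sr)
  expect_equal(dim(fm), dim(xm))
  expect_equal(fm[1, 100:900], f[100:900], tolerance = 1e-10)
})

test_that("gamma energy matches sinusoid closed forms", {
  sr <- 250
  expect_equal(gamma_energy(matrix(0, 2, 500), sr), 0)
  A <- 3
  e50 <- gamma_energy(matrix(tone(50, sr, amp = A), 1), sr)
  expect_equal(e50, A^2 / 2, tolerance = 0.1 * A^2 / 2)
  e5 <- gamma_energy(matrix(tone(5, sr, amp = A), 1), sr)
  expect_lte(e5, 0.01 * A^2 / 2)
  # sum statistic scales with the sample count
  x <- matrix(tone(50, sr, amp = A), 1)
  expect_equal(gamma_energy(x, sr, "sum"), gamma_energy(x, sr) * length(x))
})

test_that("gamma energy is approximately additive over disjoint bands", {
  sr <- 250
  g <- tone(45, sr)
  a <- tone(10, sr)
  eg <- gamma_energy(matrix(g, 1), sr)
  emix <- gamma_energy(matrix(g + a, 1), sr)
  expect_equal(emix, eg, tolerance = 0.05 * eg)
})

test_that("correlation profiles recover exact relations and category labels", {
  set.seed(51)
  n <- 40
  energies <- runif(n, 1, 5)
  labels <- rep(0:1, each = n / 2)
  features <- cbind(energies,                  # r = 1 in both classes
                    -energies + 7,             # r = -1
                    rep(1, n),                 # degenerate: zero variance
                    rnorm(n))
  prof <- feature_band_correlation(features, energies, labels)
  for (cl in c("HC", "MDD")) {
    expect_equal(prof[[cl]]$r[1], 1, tolerance = 1e-12)
    expect_equal(prof[[cl]]$r[2], -1, tolerance = 1e-12)
    expect_equal(prof[[cl]]$r[3], 0)
    expect_true(prof[[cl]]$degenerate[3])
  }
  # hand-computed Pearson on a frozen pair list
  f <- c(2.2, 3.1, 0.4, 5.5, 4.1, 3.3, 1.8, 2.9, 4.4, 0.9)
  e <- c(1.1, 2.0, 0.2, 4.9, 3.6, 3.0, 1.5, 2.2, 4.1, 0.4)
  manual <- sum((f - mean(f)) * (e - mean(e))) /
    sqrt(sum((f - mean(f))^2) * sum((e - mean(e))^2))
  lab2 <- rep(0:1, 5)
  pr2 <- feature_band_correlation(cbind(c(f, f)), c(e, e),
                                  rep(0:1, each = 10))
  expect_equal(pr2$HC$r[1], manual, tolerance = 1e-12)
  expect_equal(pr2$MDD$r[1], manual, tolerance = 1e-12)
  expect_error(feature_band_correlation(features, energies, rep(0, n)),
               "at least 3")
})

test_that("Pearson r is invariant to positive affine transforms", {
  set.seed(52)
  e <- runif(30); f <- rnorm(30)
  labels <- rep(0:1, 15)
  r0 <- feature_band_correlation(cbind(f), e, labels)$HC$r
  r1 <- feature_band_correlation(cbind(2.5 * f + 3), 0.1 * e + 7, labels)$HC$r
  expect_equal(r0, r1, tolerance = 1e-12)
})

test_that("correlation categories follow the magnitude thresholds", {
  expect_equal(unname(categorize_correlation(0.7)), c("strong", "positive"))
  expect_equal(unname(categorize_correlation(-0.5)), c("moderate", "negative"))
  expect_equal(categorize_correlation(0)[["strength"]], "weak")
  expect_equal(unname(categorize_correlation(-0.95)), c("strong", "negative"))
  expect_equal(categorize_correlation(0.3)[["strength"]], "moderate")
  expect_equal(categorize_correlation(0.29)[["strength"]], "weak")
  expect_error(categorize_correlation(1.2), "invalid input")
})

test_that("markers are features with opposite correlation signs in every fold", {
  mkprof <- function(r_hc, r_mdd) {
    mk <- function(r) data.frame(feature = seq_along(r), r = r,
                                 category = "x", degenerate = FALSE)
    structure(list(HC = mk(r_hc), MDD = mk(r_mdd)),
              class = "correlation_profile")
  }
  profiles <- list(mkprof(c(-0.8, 0.5, -0.2), c(0.9, 0.6, 0.3)),
                   mkprof(c(-0.6, 0.4, 0.1), c(0.7, 0.5, -0.2)))
  set.seed(53)
  feats <- matrix(rnorm(20 * 3), 20, 3)
  labels <- rep(0:1, 10)
  feats[labels == 1, 1] <- feats[labels == 1, 1] + 10  # non-overlapping marker
  rep <- marker_feature_report(profiles, feats, labels)
  expect_true(1L %in% rep$markers)       # opposite sign in both folds
  expect_false(2L %in% rep$markers)      # same sign in both classes
  row1 <- rep$stats[rep$stats$feature == 1L, ]
  expect_false(row1$overlap)
  expect_equal(row1$mdd_mean - row1$hc_mean, 10, tolerance = 1)
})

test_that("markers emerge from a gamma-linked generative simulation", {
  # features whose coupling to gamma energy has class-opposite sign must be
  # detected in nearly every seeded replicate
  found <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    profiles <- lapply(1:3, function(fold) {
      n <- 30
      labels <- rep(0:1, each = n / 2)
      energies <- runif(n, 1, 3) + 2 * labels
      feats <- sapply(1:8, function(j) {
        if (j <= 2) ifelse(labels == 1, 1, -1) * energies + 0.4 * rnorm(n)
        else rnorm(n)
      })
      feature_band_correlation(feats, energies, labels)
    })
    n <- 60
    labels <- rep(0:1, each = n / 2)
    feats <- matrix(rnorm(n * 8), n, 8)
    rep <- marker_feature_report(profiles, feats, labels)
    if (any(rep$markers %in% 1:2)) found <- found + 1L
  }
  expect_gte(found, 8L)
})

test_that("band ablation output has one row per band and all metric columns", {
  recs <- tiny_cohort()
  cfg <- mseegnet_config(m_r = 2, m_l = 2, sampling_rate = 128,
                         window_seconds = 1)
  model <- mseegnet(cfg, seed = 9)
  trials <- list(recs[[1]]$values[, 1:512], recs[[6]]$values[, 1:512],
                 recs[[2]]$values[, 1:512], recs[[7]]$values[, 1:512])
  labels <- c(0, 1, 0, 1)
  before <- predict(model, array(trials[[1]][, 1:128], c(4, 128, 1)))
  tab <- band_ablation(model, trials, labels)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$band, band_definitions()$name)
  expect_true(all(c("accuracy", "sensitivity", "specificity", "auc", "f1")
                  %in% names(tab)))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 100))
  after <- predict(model, array(trials[[1]][, 1:128], c(4, 128, 1)))
  expect_identical(before, after)  # ablation leaves the classifier untouched
})
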