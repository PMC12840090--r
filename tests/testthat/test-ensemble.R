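# Sub-trial segmentation and majority-vote fusion.

test_that("segmentation yields floor(N/n) consecutive windows from sample 1", {
  tr <- matrix(seq_len(2 * 2500), nrow = 2)   # 10 s at 250 Hz
  segs <- segment_trial(tr, 2, 250)
  expect_length(segs, 5)
  expect_equal(segs[[1]], tr[, 1:500])
  expect_equal(segs[[5]], tr[, 2001:2500])

  expect_length(segment_trial(tr[, 1:500, drop = FALSE], 2, 250), 1)

  # 11 s: the trailing 250 samples are discarded
  tr11 <- matrix(rnorm(2 * 2750), nrow = 2)
  segs11 <- segment_trial(tr11, 2, 250)
  expect_length(segs11, 5)
  expect_equal(segs11[[5]], tr11[, 2001:2500])

  expect_error(segment_trial(tr[, 1:499, drop = FALSE], 2, 250), "too short")
})

# Independent oracle: count labels, break ties by mean probability, then HC.
fuse_oracle <- function(labels, probs) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 != n0) return(as.integer(n1 > n0))
  m <- colMeans(probs)
  if (m[2] > m[1]) 1L else 0L
}

test_that("majority fusion matches the exhaustive counting oracle up to k = 9", {
  expect_equal(fuse_majority(c(1, 1, 0, 1, 0)), 1L)
  expect_equal(fuse_majority(rep(0, 5)), 0L)
  set.seed(31)
  for (k in 1:9) {
    grid <- expand.grid(rep(list(0:1), k))
    for (i in seq_len(nrow(grid))) {
      labels <- as.integer(grid[i, ])
      probs <- matrix(runif(2 * k), k, 2)
      probs <- probs / rowSums(probs)
      expect_identical(fuse_majority(labels, probs), fuse_oracle(labels, probs))
    }
  }
})

test_that("ties without probabilities default to the healthy-control label", {
  expect_equal(fuse_majority(c(0, 1)), 0L)
  expect_equal(fuse_majority(c(0, 1), matrix(0.5, 2, 2)), 0L)
  expect_equal(fuse_majority(c(0, 1), matrix(c(0.2, 0.4, 0.8, 0.6), 2, 2)), 1L)
  expect_error(fuse_majority(integer(0)), "no sub-trial labels")
})

test_that("fusion is permutation invariant and robust to minority flips", {
  set.seed(32)
  for (i in 1:25) {
    k <- sample(1:9, 1)
    labels <- sample(0:1, k, replace = TRUE)
    probs <- matrix(runif(2 * k), k, 2)
    perm <- sample(k)
    expect_identical(fuse_majority(labels, probs),
                     fuse_majority(labels[perm], probs[perm, , drop = FALSE]))
  }
  # flipping fewer than ceil(k/2) votes of a unanimous decision cannot flip it
  for (k in c(3, 5, 7, 9)) {
    for (flips in seq_len(ceiling(k / 2) - 1)) {
      labels <- rep(1L, k)
      labels[seq_len(flips)] <- 0L
      expect_equal(fuse_majority(labels), 1L)
    }
  }
})

test_that("ensemble prediction composes segmentation, forward and fusion", {
  model <- trained_tiny_model()
  set.seed(33)
  long <- matrix(rnorm(4 * 5 * 32), nrow = 4)   # 5 windows of the 1-s geometry
  ep <- predict_trial(model, long)
  expect_s3_class(ep, "ensemble_prediction")
  expect_length(ep$subtrial_labels, 5)
  expect_equal(dim(ep$subtrial_probabilities), c(5L, 2L))
  expect_identical(ep$fused_label,
                   fuse_majority(ep$subtrial_labels, ep$subtrial_probabilities))
  expect_equal(ep$trial_score, mean(ep$subtrial_probabilities[, 2]))

  # degenerate ensemble: one window
  ep1 <- predict_trial(model, long[, 1:32])
  expect_identical(ep1$fused_label, ep1$subtrial_labels[1])
})

test_that("voting lowers the error rate of independent noisy sub-decisions", {
  # with per-sub-trial error rate eps < 0.5, the fused error must fall
  set.seed(34)
  eps <- 0.3; k <- 5; n <- 4000
  truth <- rep(1L, n)
  fused <- vapply(seq_len(n), function(i) {
    votes <- ifelse(runif(k) < eps, 0L, 1L)
    fuse_majority(votes)
  }, integer(1))
  fused_err <- mean(fused != truth)
  binom_err <- sum(stats::dbinom(3:5, 5, eps))
  expect_lt(fused_err, eps)
  expect_equal(fused_err, binom_err, tolerance = 0.05)
})
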