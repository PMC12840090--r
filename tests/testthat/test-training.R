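# Metrics, AUC, the Adam update rule, early stopping, and optimization on
# separable data.

test_that("confusion metrics reproduce their closed forms", {
  m <- compute_metrics(list(TP = 9, FN = 1, TN = 10, FP = 0))
  expect_equal(round(unname(m), 2), c(95.00, 90.00, 100.00, 94.74))

  # degenerate: no positives predicted on a 10/11 split
  m0 <- compute_metrics(list(TP = 0, FN = 10, TN = 11, FP = 0))
  expect_equal(round(m0[["accuracy"]], 2), 52.38)
  expect_equal(m0[["sensitivity"]], 0)
  expect_equal(m0[["specificity"]], 100)
  expect_equal(m0[["f1"]], 0)

  # zero denominators (no positives present or predicted) warn and report 0
  w <- capture_warnings(mz <- compute_metrics(list(TP = 0, FN = 0, TN = 5, FP = 0)))
  expect_match(w, "sensitivity|F1", all = TRUE)
  expect_length(w, 2)
  expect_equal(mz[["sensitivity"]], 0)
  expect_equal(mz[["f1"]], 0)

  all_right <- compute_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(unname(all_right), rep(100, 4))
  expect_error(compute_metrics(list(TP = -1, TN = 1, FP = 0, FN = 0)), "negative")
})

test_that("metric identities hold on random confusion tables", {
  set.seed(41)
  for (i in 1:50) {
    counts <- as.list(stats::setNames(sample(1:40, 4, replace = TRUE),
                                      c("TP", "TN", "FP", "FN")))
    m <- compute_metrics(counts)
    with(counts, {
      expect_equal(m[["accuracy"]], 100 * (TP + TN) / (TP + TN + FP + FN))
      prec <- TP / (TP + FP)
      rec <- TP / (TP + FN)
      expect_equal(m[["f1"]], 100 * 2 * prec * rec / (prec + rec))
    })
    # balanced classes: accuracy is the mean of sensitivity and specificity
    bal <- list(TP = counts$TP, FN = counts$FN,
                TN = counts$TN, FP = counts$TP + counts$FN - counts$TN)
    if (bal$FP >= 0) {
      mb <- compute_metrics(bal)
      expect_equal(mb[["accuracy"]],
                   (mb[["sensitivity"]] + mb[["specificity"]]) / 2)
    }
  }
})

test_that("AUC equals the exhaustive pairwise-comparison oracle", {
  auc_oracle <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    100 * mean(cmp)
  }
  expect_equal(compute_auc(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1)), 100)
  hand <- list(scores = c(0.9, 0.1, 0.8, 0.4, 0.7, 0.4),
               labels = c(1, 0, 1, 0, 0, 1))
  expect_equal(compute_auc(hand$scores, hand$labels),
               auc_oracle(hand$scores, hand$labels))
  set.seed(42)
  for (i in 1:30) {
    n <- sample(4:200, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    expect_equal(compute_auc(scores, labels), auc_oracle(scores, labels))
  }
  set.seed(43)
  labels <- sample(0:1, 4000, replace = TRUE)
  expect_equal(compute_auc(rnorm(4000), labels), 50, tolerance = 3)
  expect_error(compute_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("a single Adam step matches the scalar closed form to 1e-10", {
  ctrl <- train_control()
  theta <- list(w = 0.5)
  m <- list(w = 0); v <- list(w = 0)
  g <- list(w = 0.3)
  upd <- mseegnet:::adam_step(theta, g, m, v, t = 1, ctrl, lr = ctrl$alpha)
  # closed form: with zero moments, mhat = g, vhat = g^2
  expected <- 0.5 - ctrl$alpha * 0.3 / (sqrt(0.3^2) + ctrl$epsilon)
  expect_equal(upd$params$w, expected, tolerance = 1e-10)
  expect_equal(upd$m$w, (1 - ctrl$beta1) * 0.3)
  expect_equal(upd$v$w, (1 - ctrl$beta2) * 0.3^2)

  # second step, new gradient: hand-computed recursion
  g2 <- list(w = -0.1)
  upd2 <- mseegnet:::adam_step(upd$params, g2, upd$m, upd$v, t = 2, ctrl,
                               lr = ctrl$alpha)
  m2 <- ctrl$beta1 * upd$m$w + (1 - ctrl$beta1) * (-0.1)
  v2 <- ctrl$beta2 * upd$v$w + (1 - ctrl$beta2) * 0.01
  mhat <- m2 / (1 - ctrl$beta1^2)
  vhat <- v2 / (1 - ctrl$beta2^2)
  expect_equal(upd2$params$w,
               upd$params$w - ctrl$alpha * mhat / (sqrt(vhat) + ctrl$epsilon),
               tolerance = 1e-10)
})

test_that("cross-entropy vanishes at certainty", {
  probs <- matrix(c(1, 0, 0, 1), 2, 2)  # column j = trial j
  expect_equal(mseegnet:::cross_entropy(probs, c(0L, 1L)), 0, tolerance = 1e-10)
  expect_gt(mseegnet:::cross_entropy(matrix(0.5, 2, 2), c(0L, 1L)), 0.69)
})

test_that("training on separable data reaches high accuracy and stops properly", {
  model <- trained_tiny_model()
  h <- model$history
  expect_true(all(c("epoch", "train_loss", "train_acc", "val_loss", "val_acc",
                    "lr") %in% names(h)))
  expect_gte(max(h$train_acc), 0.99)
  # best-epoch restoration: the kept parameters come from the epoch with the
  # lowest validation loss, never a later one
  expect_equal(model$best_epoch, h$epoch[which.min(h$val_loss)])
  ctrl_pat <- train_control(validation_patience = 2, max_epochs = 8)
  expect_lte(nrow(h), 8)
})

test_that("training rejects degenerate inputs", {
  tr <- tiny_trials(4)
  model <- mseegnet(tiny_config(), seed = 1)
  expect_error(
    train_mseegnet(model, tr$x, rep(0L, 8), tr$x, tr$y, train_control()),
    "both classes")
})

test_that("the learning rate follows the piecewise decay schedule", {
  tr <- tiny_trials(6, seed = 44)
  ctrl <- train_control(max_epochs = 5, lr_drop_period_epochs = 2,
                        batch_size = 12, validation_patience = 10, seed = 2)
  model <- mseegnet(tiny_config(), seed = 3)
  fit <- train_mseegnet(model, tr$x, tr$y, tr$x, tr$y, ctrl)
  expect_equal(fit$history$lr, 0.001 * c(1, 1, 0.1, 0.1, 0.01),
               tolerance = 1e-12)
})
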