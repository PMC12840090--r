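# Training: cross-entropy + L2 objective, Adam with bias-corrected moments,
# piecewise (step-decay) learning rate, early stopping on validation loss
# with best-epoch restoration.

#' Training configuration
#'
#' @param alpha Initial learning rate (default 0.001).
#' @param beta1,beta2 Adam exponential decay rates (defaults 0.9 / 0.999).
#' @param epsilon Adam stabilizer (default 1e-8).
#' @param lr_drop_factor Multiplicative learning-rate drop (default 0.1).
#' @param lr_drop_period_epochs Epochs between drops (default 10).
#' @param max_epochs Maximum training epochs (default 25).
#' @param batch_size Trials per batch; `NULL` (default) resolves to 4 times
#'   the model's sampling rate at fit time.
#' @param validation_patience Consecutive epochs without validation-loss
#'   improvement before stopping (default 5).
#' @param l2_lambda L2 penalty weight on all parameters (default 1e-4).
#' @param seed Seed controlling batch shuffling.
#' @return Object of class `train_control`.
#' @export
train_control <- function(alpha = 0.001, beta1 = 0.9, beta2 = 0.999,
                          epsilon = 1e-8, lr_drop_factor = 0.1,
                          lr_drop_period_epochs = 10L, max_epochs = 25L,
                          batch_size = NULL, validation_patience = 5L,
                          l2_lambda = 1e-4, seed = 1L) {
  stopifnot(alpha > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            epsilon > 0, lr_drop_factor > 0, lr_drop_period_epochs >= 1,
            max_epochs >= 1, validation_patience >= 1, l2_lambda >= 0)
  if (!is.null(batch_size)) stopifnot(batch_size >= 1)
  ctrl <- list(alpha = alpha, beta1 = beta1, beta2 = beta2, epsilon = epsilon,
               lr_drop_factor = lr_drop_factor,
               lr_drop_period_epochs = as.integer(lr_drop_period_epochs),
               max_epochs = as.integer(max_epochs),
               batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
               validation_patience = as.integer(validation_patience),
               l2_lambda = l2_lambda, seed = as.integer(seed))
  class(ctrl) <- "train_control"
  ctrl
}

# One Adam update. params/grads/m/v are parallel named lists of arrays;
# t is the global step (1-based). Returns updated params and moments.
adam_step <- function(params, grads, m, v, t, ctrl, lr) {
  b1 <- ctrl$beta1; b2 <- ctrl$beta2
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
    v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] - lr * (m[[nm]] / c1) / (sqrt(v[[nm]] / c2) + ctrl$epsilon)
  }
  list(params = params, m = m, v = v)
}

# Mean cross-entropy of softmax probabilities (2 x B) against 0/1 labels.
cross_entropy <- function(probs, y) {
  idx <- cbind(y + 1L, seq_along(y))
  -mean(log(pmax(probs[idx], 1e-12)))
}

l2_penalty <- function(params, lambda) {
  if (lambda == 0) return(0)
  lambda * sum(vapply(params, function(p) sum(p * p), numeric(1)))
}

eval_loss_acc <- function(model, x, y, lambda, batch_size = 256L) {
  B <- dim(x)[3]
  tot_ll <- 0; correct <- 0L
  for (s in seq(1L, B, by = batch_size)) {
    idx <- s:min(B, s + batch_size - 1L)
    fw <- mseegnet_forward(model, x[, , idx, drop = FALSE], training = FALSE)
    p <- fw$probs
    ii <- cbind(y[idx] + 1L, seq_along(idx))
    tot_ll <- tot_ll - sum(log(pmax(p[ii], 1e-12)))
    correct <- correct + sum(as.integer(p[2, ] > p[1, ]) == y[idx])
  }
  c(loss = tot_ll / B + l2_penalty(model$params, lambda), acc = correct / B)
}

#' Train the multiscale EEG network
#'
#' Minimizes cross-entropy with an L2 penalty by Adam (bias-corrected
#' moments), with a piecewise step-decayed learning rate, early stopping when
#' the validation loss has not improved for `validation_patience` consecutive
#' epochs, and restoration of the best-validation-epoch parameters.
#'
#' @param model An untrained (or warm) `mseegnet` model.
#' @param x Training trials, `(channels, samples, trials)` array.
#' @param y Training labels, 0/1 per trial (both classes required).
#' @param x_val,y_val Validation trials and labels.
#' @param control A [train_control()] object.
#' @param verbose Print per-epoch progress.
#' @return The trained model, with `$history` (per-epoch data frame of
#'   losses/accuracies/learning rate) and `$best_epoch` attached.
#' @export
train_mseegnet <- function(model, x, y, x_val, y_val,
                           control = train_control(), verbose = FALSE) {
  stopifnot(inherits(model, "mseegnet"), inherits(control, "train_control"))
  x <- check_batch(model, x)
  y <- as.integer(y)
  B_all <- dim(x)[3]
  stopifnot(length(y) == B_all, all(y %in% 0:1))
  if (length(unique(y)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  x_val <- check_batch(model, x_val)
  y_val <- as.integer(y_val)
  stopifnot(length(y_val) == dim(x_val)[3])
  bs <- control$batch_size
  if (is.null(bs)) bs <- as.integer(4 * model$config$sampling_rate)
  bs <- min(bs, B_all)
  lambda <- control$l2_lambda

  m <- lapply(model$params, function(p) array(0, dim(p) %||% length(p)))
  v <- lapply(model$params, function(p) array(0, dim(p) %||% length(p)))
  t_step <- 0L
  best <- list(loss = Inf, params = model$params, state = model$state, epoch = 0L)
  bad_epochs <- 0L
  hist <- vector("list", control$max_epochs)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(control$seed)
  for (epoch in seq_len(control$max_epochs)) {
    lr <- control$alpha *
      control$lr_drop_factor^((epoch - 1L) %/% control$lr_drop_period_epochs)
    perm <- sample.int(B_all)
    ep_ll <- 0; ep_correct <- 0L
    for (s in seq(1L, B_all, by = bs)) {
      idx <- perm[s:min(B_all, s + bs - 1L)]
      xb <- x[, , idx, drop = FALSE]
      yb <- y[idx]
      fw <- mseegnet_forward(model, xb, training = TRUE, keep_cache = TRUE)
      model$state <- fw$state
      p <- fw$probs
      nb <- length(idx)
      ii <- cbind(yb + 1L, seq_len(nb))
      batch_ll <- -sum(log(pmax(p[ii], 1e-12)))
      if (!is.finite(batch_ll)) {
        stop(sprintf("NaN/Inf loss at epoch %d, step %d: aborting (lr=%g)",
                     epoch, t_step + 1L, lr), call. = FALSE)
      }
      ep_ll <- ep_ll + batch_ll
      ep_correct <- ep_correct + sum(as.integer(p[2, ] > p[1, ]) == yb)
      dlogits <- p
      dlogits[ii] <- dlogits[ii] - 1
      dlogits <- dlogits / nb
      grads <- mseegnet_backward(model, fw, dlogits)
      if (lambda > 0) {
        for (nm in names(grads)) {
          grads[[nm]] <- grads[[nm]] + 2 * lambda * model$params[[nm]]
        }
      }
      t_step <- t_step + 1L
      upd <- adam_step(model$params, grads, m, v, t_step, control, lr)
      model$params <- upd$params
      m <- upd$m; v <- upd$v
    }
    val <- eval_loss_acc(model, x_val, y_val, lambda)
    hist[[epoch]] <- data.frame(
      epoch = epoch,
      train_loss = ep_ll / B_all + l2_penalty(model$params, lambda),
      train_acc = ep_correct / B_all,
      val_loss = val["loss"], val_acc = val["acc"], lr = lr)
    if (verbose) {
      message(sprintf("epoch %2d: train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      epoch, hist[[epoch]]$train_loss, hist[[epoch]]$train_acc,
                      val["loss"], val["acc"]))
    }
    if (val["loss"] < best$loss) {
      best <- list(loss = val["loss"], params = model$params,
                   state = model$state, epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= control$validation_patience) break
    }
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  model$params <- best$params
  model$state <- best$state
  model$trained <- TRUE
  model$history <- do.call(rbind, Filter(Negate(is.null), hist))
  rownames(model$history) <- NULL
  model$best_epoch <- best$epoch
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot the training history of a fitted model
#'
#' @param x A trained `mseegnet` model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.mseegnet <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history", call. = FALSE)
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "b",
                    pch = c(1, 2), lty = 1, xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), pch = c(1, 2),
                   col = c(1, 2), lty = 1, bty = "n")
  invisible(x)
}
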