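# Model construction and the forward/backward passes.
#
# The network composes five mappings: hemispheric spatial integration (one
# spatial kernel spanning each hemisphere's channels), spatial analysis (F1
# filters of extent 2 collapsing the two hemispheric rows), a multiscale bank
# of three depthwise temporal convolutions (kernels S1 >= S2 >= S3, depth D)
# concatenated and average-pooled, two separable high-level blocks with a
# pointwise projection skip, global pooling to the learned-feature vector, and
# a fully connected softmax classifier.

# Channel widths derived from the configuration.
model_widths <- function(cfg) {
  Cm <- 3L * cfg$D * cfg$F1          # concatenated multiscale width
  list(Cm = Cm, CmD = Cm * cfg$D, F3D = cfg$F3 * cfg$D)
}

#' Build an untrained multiscale EEG network
#'
#' Allocates and initializes all learnable parameters (Glorot-uniform weights,
#' zero biases, unit/zero normalization affine terms) for the architecture
#' described by `config`.
#'
#' @param config An [mseegnet_config()] object.
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `mseegnet` with elements `config`, `params`
#'   (named list of parameter arrays), and `state` (batch-normalization
#'   running statistics).
#' @examples
#' model <- mseegnet(mseegnet_config(), seed = 1)
#' sum(count_parameters(model)$count) # 34812
#' @export
mseegnet <- function(config, seed = 1L) {
  validate_config(config)
  w <- model_widths(config)
  glorot <- function(dims, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    array(stats::runif(prod(dims), -lim, lim), dims)
  }
  S <- config$scales
  F1 <- config$F1; D <- config$D; F2 <- config$F2; F3 <- config$F3
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  p <- list(
    pre_r_w = glorot(c(1, config$m_r), config$m_r, 1), pre_r_b = 0,
    pre_l_w = glorot(c(1, config$m_l), config$m_l, 1), pre_l_b = 0,
    fs_w = glorot(c(F1, 2), 2, F1), fs_b = numeric(F1),
    fs_g = rep(1, F1), fs_be = numeric(F1),
    ms1_w = glorot(c(S[1], F1 * D), S[1], S[1] * D), ms1_b = numeric(F1 * D),
    ms1_g = rep(1, F1 * D), ms1_be = numeric(F1 * D),
    ms2_w = glorot(c(S[2], F1 * D), S[2], S[2] * D), ms2_b = numeric(F1 * D),
    ms2_g = rep(1, F1 * D), ms2_be = numeric(F1 * D),
    ms3_w = glorot(c(S[3], F1 * D), S[3], S[3] * D), ms3_b = numeric(F1 * D),
    ms3_g = rep(1, F1 * D), ms3_be = numeric(F1 * D),
    h1_w = glorot(c(S[3], w$CmD), S[3], S[3] * D), h1_b = numeric(w$CmD),
    h1_g = rep(1, w$CmD), h1_be = numeric(w$CmD),
    p1_w = glorot(c(F3, w$CmD), w$CmD, F3), p1_b = numeric(F3),
    p1_g = rep(1, F3), p1_be = numeric(F3),
    h2_w = glorot(c(S[3], w$F3D), S[3], S[3] * D), h2_b = numeric(w$F3D),
    h2_g = rep(1, w$F3D), h2_be = numeric(w$F3D),
    p2_w = glorot(c(F2, w$F3D), w$F3D, F2), p2_b = numeric(F2),
    p2_g = rep(1, F2), p2_be = numeric(F2),
    skip_w = glorot(c(F2, w$Cm), w$Cm, F2), skip_b = numeric(F2),
    fc_w = glorot(c(2, F2), F2, 2), fc_b = numeric(2)
  )
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  model <- list(config = config, params = p,
                state = list(fs = NULL, ms1 = NULL, ms2 = NULL, ms3 = NULL,
                             h1 = NULL, p1 = NULL, h2 = NULL, p2 = NULL),
                trained = FALSE, history = NULL, seed = as.integer(seed))
  class(model) <- "mseegnet"
  model
}

check_batch <- function(model, x) {
  cfg <- model$config
  m <- cfg$m_r + cfg$m_l
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 3L) {
    stop("shape error: expected trials as a (channels, samples, batch) array",
         call. = FALSE)
  }
  d <- dim(x)
  if (d[1] != m || d[2] != cfg$n) {
    stop(sprintf(
      "shape error: expected %d x %d x batch (channels x samples), got %d x %d x %d",
      m, cfg$n, d[1], d[2], d[3]), call. = FALSE)
  }
  if (!all(is.finite(x))) stop("non-finite values in input batch", call. = FALSE)
  x
}

# Activation/normalization sub-block in the configured order. The default
# recipe (ReLU then batch/layer/one-group-group normalization) runs through
# fused C++ kernels; every other combination uses the generic R layers.
actnorm_fwd <- function(x, kind_norm, gamma, beta, groups, cfg, training, state) {
  if (cfg$activation == "relu" && cfg$norm_after_activation &&
      (kind_norm %in% c("batch", "layer") ||
       (kind_norm == "group" && groups == 1L))) {
    d <- dim(x)
    kind <- if (kind_norm == "batch") 0L else 1L
    if (kind == 0L && !training && !is.null(state) && state$count > 0) {
      out <- .relu_norm_fwd(x, gamma, beta, d[1], d[2], d[3], 0L, FALSE,
                            state$mean, state$var)
      return(list(y = out$y, cache = NULL, state = state))
    }
    out <- .relu_norm_fwd(x, gamma, beta, d[1], d[2], d[3], kind, TRUE, NULL, NULL)
    y <- out$y
    newstate <- state
    if (kind == 0L && training) {
      if (is.null(state) || is.null(state$count) || state$count == 0) {
        newstate <- list(mean = out$mu, var = out$var, count = 1L)
      } else {
        newstate <- list(mean = 0.9 * state$mean + 0.1 * out$mu,
                         var = 0.9 * state$var + 0.1 * out$var,
                         count = state$count + 1L)
      }
    }
    cache <- list(fast = TRUE, kind = kind, xhat = out$xhat, mu = out$mu,
                  inv = out$inv, gamma = gamma, dims = d)
    return(list(y = y, cache = cache, state = newstate))
  }
  if (cfg$norm_after_activation) {
    a <- act_fwd(x, cfg$activation)
    n <- norm_fwd(a$y, kind_norm, gamma, beta, groups, training, state)
    list(y = n$y, cache = list(order = "an", a = a$cache, n = n$cache),
         state = n$state)
  } else {
    n <- norm_fwd(x, kind_norm, gamma, beta, groups, training, state)
    a <- act_fwd(n$y, cfg$activation)
    list(y = a$y, cache = list(order = "na", a = a$cache, n = n$cache),
         state = n$state)
  }
}

actnorm_bwd <- function(dy, cache) {
  if (isTRUE(cache$fast)) {
    d <- cache$dims
    out <- .relu_norm_bwd(dy, cache$xhat, cache$mu, cache$inv, cache$gamma,
                          d[1], d[2], d[3], cache$kind)
    return(list(dx = out$dx, dgamma = out$dgamma, dbeta = out$dbeta))
  }
  if (cache$order == "an") {
    nb <- norm_bwd(dy, cache$n)
    dx <- act_bwd(nb$dx, cache$a)
    list(dx = dx, dgamma = nb$dgamma, dbeta = nb$dbeta)
  } else {
    da <- act_bwd(dy, cache$a)
    nb <- norm_bwd(da, cache$n)
    list(dx = nb$dx, dgamma = nb$dgamma, dbeta = nb$dbeta)
  }
}

# Full forward pass. Returns logits (2 x B), probs (2 x B), features (F2 x B),
# intermediate shapes, layer caches (when keep_cache) and updated norm state.
mseegnet_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  st <- model$state
  x <- check_batch(model, x)
  d <- dim(x); B <- d[3]
  shapes <- list(input = c(cfg$m_r + cfg$m_l, cfg$n))
  caches <- if (keep_cache) list() else NULL
  keep <- function(name, val) if (keep_cache) caches[[name]] <<- val

  # F_Pre: one spatial kernel per hemisphere, concatenated to two rows
  xr <- x[seq_len(cfg$m_r), , , drop = FALSE]
  xl <- x[cfg$m_r + seq_len(cfg$m_l), , , drop = FALSE]
  pr <- chmix_fwd(xr, p$pre_r_w, p$pre_r_b); keep("pre_r", pr$cache)
  pl <- chmix_fwd(xl, p$pre_l_w, p$pre_l_b); keep("pre_l", pl$cache)
  o1 <- array(0, c(2L, cfg$n, B))
  o1[1, , ] <- pr$y; o1[2, , ] <- pl$y
  shapes$pre <- c(2L, cfg$n)

  # F_S: F1 spatial filters of extent 2, activation + spatial normalization
  fsc <- chmix_fwd(o1, p$fs_w, p$fs_b); keep("fs_conv", fsc$cache)
  fsn <- actnorm_fwd(fsc$y, cfg$spatial_norm, p$fs_g, p$fs_be, cfg$gn_groups,
                     cfg, training, st$fs)
  st$fs <- fsn$state; keep("fs_an", fsn$cache)
  o2 <- fsn$y
  shapes$fs <- c(cfg$F1, cfg$n)

  # F_MS: three depthwise branches, concatenated in scale order, mid pooling
  branches <- vector("list", 3L)
  for (i in 1:3) {
    wn <- paste0("ms", i)
    dwc <- dwconv_fwd_layer(o2, p[[paste0(wn, "_w")]], p[[paste0(wn, "_b")]], cfg$D)
    keep(paste0(wn, "_conv"), dwc$cache)
    an <- actnorm_fwd(dwc$y, cfg$temporal_norm, p[[paste0(wn, "_g")]],
                      p[[paste0(wn, "_be")]], cfg$gn_groups, cfg, training, st[[wn]])
    st[[wn]] <- an$state; keep(paste0(wn, "_an"), an$cache)
    branches[[i]] <- an$y
    shapes[[paste0("ms", i)]] <- c(cfg$F1 * cfg$D, cfg$n)
  }
  wdt <- model_widths(cfg)
  o3 <- array(0, c(wdt$Cm, cfg$n, B))
  o3[seq_len(cfg$F1 * cfg$D), , ] <- branches[[1]]
  o3[cfg$F1 * cfg$D + seq_len(cfg$F1 * cfg$D), , ] <- branches[[2]]
  o3[2L * cfg$F1 * cfg$D + seq_len(cfg$F1 * cfg$D), , ] <- branches[[3]]
  shapes$ms_concat <- c(wdt$Cm, cfg$n)
  mp <- pool_fwd(o3, cfg$pool_window, cfg$pool_stride, cfg$pooling_kind[1])
  keep("midpool", mp$cache)
  o4 <- mp$y
  shapes$midpool <- dim(o4)[1:2]

  # F_HFL: two separable blocks + projection skip
  h1 <- dwconv_fwd_layer(o4, p$h1_w, p$h1_b, cfg$D); keep("h1_conv", h1$cache)
  h1a <- actnorm_fwd(h1$y, cfg$temporal_norm, p$h1_g, p$h1_be, cfg$gn_groups,
                     cfg, training, st$h1)
  st$h1 <- h1a$state; keep("h1_an", h1a$cache)
  shapes$hfl_dw1 <- dim(h1a$y)[1:2]
  p1 <- chmix_fwd(h1a$y, p$p1_w, p$p1_b); keep("p1_conv", p1$cache)
  p1a <- actnorm_fwd(p1$y, cfg$temporal_norm, p$p1_g, p$p1_be, cfg$gn_groups,
                     cfg, training, st$p1)
  st$p1 <- p1a$state; keep("p1_an", p1a$cache)
  shapes$hfl_pw1 <- dim(p1a$y)[1:2]
  h2 <- dwconv_fwd_layer(p1a$y, p$h2_w, p$h2_b, cfg$D); keep("h2_conv", h2$cache)
  h2a <- actnorm_fwd(h2$y, cfg$temporal_norm, p$h2_g, p$h2_be, cfg$gn_groups,
                     cfg, training, st$h2)
  st$h2 <- h2a$state; keep("h2_an", h2a$cache)
  shapes$hfl_dw2 <- dim(h2a$y)[1:2]
  p2 <- chmix_fwd(h2a$y, p$p2_w, p$p2_b); keep("p2_conv", p2$cache)
  p2a <- actnorm_fwd(p2$y, cfg$temporal_norm, p$p2_g, p$p2_be, cfg$gn_groups,
                     cfg, training, st$p2)
  st$p2 <- p2a$state; keep("p2_an", p2a$cache)
  shapes$hfl_pw2 <- dim(p2a$y)[1:2]
  sk <- chmix_fwd(o4, p$skip_w, p$skip_b); keep("skip", sk$cache)
  o8 <- p2a$y + sk$y
  shapes$hfl_add <- dim(o8)[1:2]
  gp <- gap_fwd(o8, cfg$pooling_kind[2]); keep("gap", gp$cache)
  features <- gp$y                         # (F2, B)
  shapes$gap <- c(cfg$F2, 1L)

  # F_C
  fc <- chmix_fwd(array(features, c(cfg$F2, 1L, B)), p$fc_w, p$fc_b)
  keep("fc", fc$cache)
  logits <- matrix(fc$y, 2L, B)
  shapes$fc <- c(2L, 1L)
  probs <- softmax_rows(logits)

  list(probs = probs, logits = logits, features = features, shapes = shapes,
       caches = caches, state = st)
}

# Backward pass from d(loss)/d(logits); returns gradients named like params.
mseegnet_backward <- function(model, fw, dlogits) {
  cfg <- model$config
  caches <- fw$caches
  B <- ncol(dlogits)
  g <- list()
  fcb <- chmix_bwd(array(dlogits, c(2L, 1L, B)), caches$fc)
  g$fc_w <- fcb$dW; g$fc_b <- fcb$db
  dfeat <- matrix(fcb$dx, cfg$F2, B)
  do8 <- gap_bwd(dfeat, caches$gap)
  # skip path
  skb <- chmix_bwd(do8, caches$skip)
  g$skip_w <- skb$dW; g$skip_b <- skb$db
  # separable block 2
  an <- actnorm_bwd(do8, caches$p2_an)
  g$p2_g <- an$dgamma; g$p2_be <- an$dbeta
  cb <- chmix_bwd(an$dx, caches$p2_conv)
  g$p2_w <- cb$dW; g$p2_b <- cb$db
  an <- actnorm_bwd(cb$dx, caches$h2_an)
  g$h2_g <- an$dgamma; g$h2_be <- an$dbeta
  db <- dwconv_bwd_layer(an$dx, caches$h2_conv)
  g$h2_w <- db$dW; g$h2_b <- db$db
  # separable block 1
  an <- actnorm_bwd(db$dx, caches$p1_an)
  g$p1_g <- an$dgamma; g$p1_be <- an$dbeta
  cb <- chmix_bwd(an$dx, caches$p1_conv)
  g$p1_w <- cb$dW; g$p1_b <- cb$db
  an <- actnorm_bwd(cb$dx, caches$h1_an)
  g$h1_g <- an$dgamma; g$h1_be <- an$dbeta
  db <- dwconv_bwd_layer(an$dx, caches$h1_conv)
  g$h1_w <- db$dW; g$h1_b <- db$db
  do4 <- db$dx + skb$dx
  do3 <- pool_bwd(do4, caches$midpool)
  # multiscale branches
  FD <- cfg$F1 * cfg$D
  do2 <- 0
  for (i in 1:3) {
    wn <- paste0("ms", i)
    dbr <- do3[(i - 1L) * FD + seq_len(FD), , , drop = FALSE]
    an <- actnorm_bwd(dbr, caches[[paste0(wn, "_an")]])
    g[[paste0(wn, "_g")]] <- an$dgamma; g[[paste0(wn, "_be")]] <- an$dbeta
    db <- dwconv_bwd_layer(an$dx, caches[[paste0(wn, "_conv")]])
    g[[paste0(wn, "_w")]] <- db$dW; g[[paste0(wn, "_b")]] <- db$db
    do2 <- do2 + db$dx
  }
  # spatial analysis
  an <- actnorm_bwd(do2, caches$fs_an)
  g$fs_g <- an$dgamma; g$fs_be <- an$dbeta
  cb <- chmix_bwd(an$dx, caches$fs_conv)
  g$fs_w <- cb$dW; g$fs_b <- cb$db
  do1 <- cb$dx
  # hemispheric integration
  prb <- chmix_bwd(do1[1, , , drop = FALSE], caches$pre_r)
  plb <- chmix_bwd(do1[2, , , drop = FALSE], caches$pre_l)
  g$pre_r_w <- prb$dW; g$pre_r_b <- prb$db
  g$pre_l_w <- plb$dW; g$pre_l_b <- plb$db
  g
}

#' Class probabilities, labels or learned features for a batch of trials
#'
#' @param object A trained or untrained `mseegnet` model.
#' @param newdata Array of trials, `(channels, samples, batch)` (a single
#'   `channels x samples` matrix is promoted to a batch of one).
#' @param type `"prob"` for the `batch x 2` softmax probability matrix,
#'   `"class"` for hard 0/1 labels, `"features"` for the `batch x F2` matrix
#'   of global-pooled learned features.
#' @param batch_size Trials processed per forward pass.
#' @param ... Unused.
#' @return Matrix or vector according to `type`.
#' @export
predict.mseegnet <- function(object, newdata, type = c("prob", "class", "features"),
                             batch_size = 256L, ...) {
  type <- match.arg(type)
  x <- check_batch(object, newdata)
  B <- dim(x)[3]
  probs <- matrix(0, B, 2L)
  feats <- matrix(0, B, object$config$F2)
  for (s in seq(1L, B, by = batch_size)) {
    idx <- s:min(B, s + batch_size - 1L)
    fw <- mseegnet_forward(object, x[, , idx, drop = FALSE], training = FALSE)
    probs[idx, ] <- t(fw$probs)
    feats[idx, ] <- t(fw$features)
  }
  colnames(probs) <- c("HC", "MDD")
  switch(type,
         prob = probs,
         class = as.integer(probs[, 2] > probs[, 1]),
         features = feats)
}

#' Extract the global-pooled learned features
#'
#' Returns the feature vector produced by the global pooling layer, one row
#' per trial, before the fully connected classifier. Applying the model's
#' fully connected layer and a softmax to these features reproduces
#' `predict(model, x, type = "prob")`.
#'
#' @inheritParams predict.mseegnet
#' @param model A `mseegnet` model.
#' @param x Trial batch array `(channels, samples, batch)`.
#' @return `batch x F2` numeric matrix.
#' @export
extract_gap_features <- function(model, x, batch_size = 256L) {
  predict(model, x, type = "features", batch_size = batch_size)
}

#' Intermediate output shapes of the network
#'
#' Runs a single zero trial through the model and records the
#' `(channels, samples)` shape after every stage.
#'
#' @param model A `mseegnet` model.
#' @return Named list of integer shape vectors.
#' @export
model_shapes <- function(model) {
  cfg <- model$config
  x <- array(0, c(cfg$m_r + cfg$m_l, cfg$n, 1L))
  mseegnet_forward(model, x, training = FALSE)$shapes
}

#' @export
print.mseegnet <- function(x, ...) {
  cfg <- x$config
  cat("Multiscale spatial-temporal EEG network\n")
  cat(sprintf("  input %d channels x %d samples (%g s at %g Hz)\n",
              cfg$m_r + cfg$m_l, cfg$n, cfg$window_seconds, cfg$sampling_rate))
  cat(sprintf("  learnable parameters: %d%s\n",
              total_parameters(x),
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

#' @export
summary.mseegnet <- function(object, ...) {
  rep <- count_parameters(object)
  print(object)
  cat("\n")
  print(rep)
  invisible(rep)
}

#' @export
coef.mseegnet <- function(object, ...) {
  unlist(object$params)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a plain RDS file holding configuration, parameters and
#' normalization state; the configuration is additionally echoed as a JSON
#' sidecar next to the checkpoint for inspection.
#'
#' @param model A `mseegnet` model.
#' @param path Checkpoint file path.
#' @return `save_mseegnet` returns `path` invisibly; `load_mseegnet` returns
#'   the restored model.
#' @export
save_mseegnet <- function(model, path) {
  saveRDS(model, path)
  cfg_json <- jsonlite::toJSON(unclass(model$config), auto_unbox = TRUE, digits = NA)
  writeLines(cfg_json, paste0(path, ".config.json"))
  invisible(path)
}

#' @rdname save_mseegnet
#' @export
load_mseegnet <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "mseegnet"))
  model
}
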