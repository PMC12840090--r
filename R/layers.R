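# Internal layer primitives. Every activation map is stored channel-first as a
# (C, N, B) array: channels x time x batch. In that layout matrix(x, nrow = C)
# exposes channels as rows with one column per (time, batch) pair, which makes
# per-channel broadcasting and pointwise (1x1) convolutions plain BLAS gemms.

NORM_EPS <- 1e-5

## ---- activations ------------------------------------------------------------

act_fwd <- function(x, kind) {
  switch(kind,
    relu = {
      y <- x * (x > 0)
      # for ReLU the output alone determines the gradient mask
      list(y = y, cache = list(kind = kind, y = y))
    },
    leaky_relu = {
      y <- ifelse(x > 0, x, 0.01 * x)
      list(y = y, cache = list(kind = kind, x = x))
    },
    clipped_relu = {
      y <- pmin(pmax(x, 0), 6)
      list(y = y, cache = list(kind = kind, x = x))
    },
    tanh = {
      y <- tanh(x)
      list(y = y, cache = list(kind = kind, y = y))
    },
    swish = {
      s <- 1 / (1 + exp(-x))
      list(y = x * s, cache = list(kind = kind, x = x, s = s))
    },
    gelu = {
      # exact Gaussian error-function form: x * Phi(x)
      p <- stats::pnorm(x)
      list(y = x * p, cache = list(kind = kind, x = x, p = p))
    },
    stop("unknown activation: ", kind)
  )
}

act_bwd <- function(dy, cache) {
  switch(cache$kind,
    relu = dy * (cache$y > 0),
    leaky_relu = dy * ifelse(cache$x > 0, 1, 0.01),
    clipped_relu = dy * (cache$x > 0 & cache$x < 6),
    tanh = dy * (1 - cache$y^2),
    swish = dy * (cache$s + cache$x * cache$s * (1 - cache$s)),
    gelu = dy * (cache$p + cache$x * stats::dnorm(cache$x)),
    stop("unknown activation cache")
  )
}

## ---- normalization ----------------------------------------------------------

# Generic normalization over (C, N, B). Statistics are pooled over:
#   batch: (N, B) per channel (training) or running statistics (evaluation);
#   group: (C/G channels, N) per (group, sample) -- batch independent;
#   layer: (C, N) per sample.
# The learnable affine (gamma, beta) is always per channel, so every kind
# carries the same 2*C learnable parameters.

norm_fwd <- function(x, kind, gamma, beta, groups = 1L, training = TRUE,
                     state = NULL, momentum = 0.1) {
  d <- dim(x); C <- d[1]; N <- d[2]; B <- d[3]
  # one group over all channels has exactly the per-sample statistics of
  # layer normalization; route it through the cheaper path
  if (kind == "group" && groups == 1L) kind <- "layer"
  if (kind == "batch") {
    if (training || is.null(state) || is.null(state$count) || state$count == 0) {
      mu <- .rowMeans(x, C, N * B)
      v <- .rowMeans(x * x, C, N * B) - mu^2
      v[v < 0] <- 0
      if (training) {
        if (is.null(state) || is.null(state$count) || state$count == 0) {
          state <- list(mean = mu, var = v, count = 1L)
        } else {
          state$mean <- (1 - momentum) * state$mean + momentum * mu
          state$var <- (1 - momentum) * state$var + momentum * v
          state$count <- state$count + 1L
        }
      }
    } else {
      mu <- state$mean
      v <- state$var
    }
    inv <- 1 / sqrt(v + NORM_EPS)
    xhat <- (x - mu) * inv          # per-channel vectors recycle down dim 1
    y <- gamma * xhat + beta
    cache <- list(kind = kind, xhat = xhat, inv = inv, gamma = gamma,
                  dims = d, training = training)
  } else if (kind == "group") {
    G <- groups; Cg <- C %/% G
    # (Cg, G, N, B) -> (Cg, N, G, B): one column per (group, sample)
    xg <- matrix(aperm(array(x, c(Cg, G, N, B)), c(1, 3, 2, 4)), nrow = Cg * N)
    mu <- colMeans(xg)
    v <- colMeans(xg^2) - mu^2
    v[v < 0] <- 0
    inv <- 1 / sqrt(v + NORM_EPS)
    xhatg <- (xg - rep(mu, each = Cg * N)) * rep(inv, each = Cg * N)
    xhat <- matrix(aperm(array(xhatg, c(Cg, N, G, B)), c(1, 3, 2, 4)), nrow = C)
    dim(xhat) <- d
    y <- gamma * xhat + beta
    cache <- list(kind = kind, xhat = xhat, inv = inv, gamma = gamma,
                  dims = d, groups = G)
  } else if (kind == "layer") {
    CN <- C * N
    mu <- .colMeans(x, CN, B)
    v <- .colMeans(x * x, CN, B) - mu^2
    v[v < 0] <- 0
    inv <- 1 / sqrt(v + NORM_EPS)
    xhat <- (x - rep(mu, each = CN)) * rep(inv, each = CN)
    y <- gamma * xhat + beta
    cache <- list(kind = kind, xhat = xhat, inv = inv, gamma = gamma, dims = d)
  } else {
    stop("unknown normalization: ", kind)
  }
  dim(y) <- d
  list(y = y, cache = cache, state = state)
}

norm_bwd <- function(dy, cache) {
  d <- cache$dims; C <- d[1]; N <- d[2]; B <- d[3]
  xhat <- cache$xhat
  dgamma <- .rowSums(dy * xhat, C, N * B)
  dbeta <- .rowSums(dy, C, N * B)
  dxhat <- dy * cache$gamma
  kind <- cache$kind
  if (kind == "batch") {
    if (isTRUE(cache$training)) {
      m1 <- .rowMeans(dxhat, C, N * B)
      m2 <- .rowMeans(dxhat * xhat, C, N * B)
      dx <- cache$inv * (dxhat - m1 - xhat * m2)
    } else {
      dx <- dxhat * cache$inv
    }
  } else if (kind == "group") {
    G <- cache$groups; Cg <- C %/% G
    to_g <- function(m) matrix(aperm(array(m, c(Cg, G, N, B)), c(1, 3, 2, 4)),
                               nrow = Cg * N)
    from_g <- function(m) matrix(aperm(array(m, c(Cg, N, G, B)), c(1, 3, 2, 4)),
                                 nrow = C)
    dxh <- to_g(dxhat)
    xhg <- to_g(xhat)
    m1 <- colMeans(dxh)
    m2 <- colMeans(dxh * xhg)
    M <- Cg * N
    dxg <- (dxh - rep(m1, each = M) - xhg * rep(m2, each = M)) *
      rep(cache$inv, each = M)
    dx <- from_g(dxg)
  } else { # layer
    CN <- C * N
    m1 <- .colMeans(dxhat, CN, B)
    m2 <- .colMeans(dxhat * xhat, CN, B)
    dx <- (dxhat - rep(m1, each = CN) - xhat * rep(m2, each = CN)) *
      rep(cache$inv, each = CN)
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- channel-mixing convolutions (gemm) -------------------------------------

# y[f, t, b] = sum_c W[f, c] x[c, t, b] + b[f]; covers the hemispheric spatial
# convolutions (1 x m kernels), the 2 x 1 spatial filters, every pointwise
# (1 x 1) convolution and, with N = 1, the fully connected layer. Implemented
# as dgemm on the raw (C, N*B) layout without reshape copies.
chmix_fwd <- function(x, W, b) {
  d <- dim(x)
  y <- .chmix_fwd(x, W, b, d[1], d[2], d[3])
  list(y = y, cache = list(x = x, W = W))
}

chmix_bwd <- function(dy, cache) {
  d <- dim(cache$x)
  out <- .chmix_bwd(dy, cache$x, cache$W, d[1], d[2], d[3])
  list(dx = out$dx, dW = out$dW, db = out$db)
}

## ---- depthwise temporal convolution (Rcpp kernels) --------------------------

dw_pad_left <- function(K) {
  if (K %% 2L == 1L) (K - 1L) %/% 2L else K %/% 2L - 1L
}

dwconv_fwd_layer <- function(x, W, b, D) {
  d <- dim(x)
  K <- nrow(W)
  y <- .dwconv_fwd(x, as.numeric(W), b, d[1], d[2], d[3], D, dw_pad_left(K))
  list(y = y, cache = list(x = x, W = W, D = D, K = K))
}

dwconv_bwd_layer <- function(dy, cache) {
  d <- dim(cache$x)
  padL <- dw_pad_left(cache$K)
  dx <- .dwconv_bwd_x(dy, as.numeric(cache$W), d[1], d[2], d[3], cache$D, padL)
  wg <- .dwconv_bwd_w(cache$x, dy, d[1], d[2], d[3], cache$D, cache$K, padL)
  list(dx = dx, dW = wg$dW, db = wg$db)
}

## ---- pooling ----------------------------------------------------------------

pool_fwd <- function(x, window, stride, kind) {
  d <- dim(x); C <- d[1]; N <- d[2]; B <- d[3]
  L <- (N - window) %/% stride + 1L
  if (kind == "average" && window == stride && N == window * L) {
    y <- .avgpool_fwd(x, C, N, B, window)
    return(list(y = y,
                cache = list(kind = kind, window = window, stride = stride,
                             dims = d, L = L, fast = TRUE)))
  }
  y <- array(0, c(C, L, B))
  amax <- if (kind == "max") array(0L, c(C, L, B)) else NULL
  for (j in seq_len(L)) {
    idx <- ((j - 1L) * stride + 1L):((j - 1L) * stride + window)
    slab <- x[, idx, , drop = FALSE]
    if (kind == "average") {
      y[, j, ] <- colMeans(aperm(slab, c(2, 1, 3)))
    } else {
      sl2 <- matrix(aperm(slab, c(2, 1, 3)), nrow = window)
      w <- max.col(t(sl2), ties.method = "first")
      y[, j, ] <- sl2[cbind(w, seq_along(w))]
      amax[, j, ] <- w
    }
  }
  list(y = y, cache = list(kind = kind, window = window, stride = stride,
                           dims = d, L = L, fast = FALSE, amax = amax))
}

pool_bwd <- function(dy, cache) {
  d <- cache$dims; C <- d[1]; N <- d[2]; B <- d[3]
  w <- cache$window; s <- cache$stride; L <- cache$L
  if (isTRUE(cache$fast)) {
    return(.avgpool_bwd(dy, C, N, B, w))
  }
  dx <- array(0, d)
  for (j in seq_len(L)) {
    idx <- ((j - 1L) * s + 1L):((j - 1L) * s + w)
    if (cache$kind == "average") {
      dx[, idx, ] <- dx[, idx, ] + array(rep(dy[, j, ] / w, each = 1),
                                         c(C, 1, B))[, rep(1, w), ]
    } else {
      amax <- cache$amax[, j, ]
      dslab <- array(0, c(w, C, B))
      dslab[cbind(as.vector(amax), rep(seq_len(C), times = B),
                  rep(seq_len(B), each = C))] <- as.vector(dy[, j, ])
      dx[, idx, ] <- dx[, idx, ] + aperm(dslab, c(2, 1, 3))
    }
  }
  dx
}

gap_fwd <- function(x, kind) {
  d <- dim(x)
  if (kind == "average") {
    y <- colMeans(aperm(x, c(2, 1, 3)))  # (C, B)
    list(y = matrix(y, d[1], d[3]), cache = list(kind = kind, dims = d))
  } else {
    x2 <- matrix(aperm(x, c(2, 1, 3)), nrow = d[2])
    w <- max.col(t(x2), ties.method = "first")
    y <- x2[cbind(w, seq_along(w))]
    list(y = matrix(y, d[1], d[3]),
         cache = list(kind = kind, dims = d, amax = w))
  }
}

gap_bwd <- function(dy, cache) {
  d <- cache$dims
  if (cache$kind == "average") {
    dx <- aperm(array(rep(as.vector(dy) / d[2], each = d[2]),
                      c(d[2], d[1], d[3])), c(2, 1, 3))
  } else {
    dx2 <- matrix(0, d[2], d[1] * d[3])
    dx2[cbind(cache$amax, seq_len(d[1] * d[3]))] <- as.vector(dy)
    dx <- aperm(array(dx2, c(d[2], d[1], d[3])), c(2, 1, 3))
  }
  dx
}

softmax_rows <- function(a) {
  # a: (classes, B); stable column-wise softmax
  m <- apply(a, 2, max)
  e <- exp(sweep(a, 2, m))
  sweep(e, 2, colSums(e), "/")
}
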