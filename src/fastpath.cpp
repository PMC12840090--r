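#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Fused fast-path kernels for the default layer recipe
// (convolution -> ReLU -> normalization) and the gemm-shaped channel-mixing
// convolutions. The generic R implementations remain the reference for every
// other activation/normalization/order combination.

static const double EPS = 1e-5;

// ---- ReLU + normalization, activation first ---------------------------------
// kind 0: batch statistics (per channel over time x batch)
// kind 1: per-sample statistics (layer norm / one-group group norm)

// [[Rcpp::export(name = ".relu_norm_fwd")]]
List relu_norm_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                   int C, int N, int B, int kind, bool training,
                   Nullable<NumericVector> rmean_, Nullable<NumericVector> rvar_) {
  R_xlen_t total = static_cast<R_xlen_t>(C) * N * B;
  NumericVector y(no_init(total));
  y.attr("dim") = IntegerVector::create(C, N, B);
  const double* xp = x.begin();
  double* yp = y.begin();
  const double* gp = gamma.begin();
  const double* bp = beta.begin();

  if (kind == 0 && !training) {
    // evaluation mode: running statistics, no cache needed
    NumericVector rmean(rmean_), rvar(rvar_);
    std::vector<double> scale(C), shift(C);
    for (int c = 0; c < C; ++c) {
      double inv = 1.0 / std::sqrt(rvar[c] + EPS);
      scale[c] = gp[c] * inv;
      shift[c] = bp[c] - gp[c] * rmean[c] * inv;
    }
    R_xlen_t cols = static_cast<R_xlen_t>(N) * B;
    for (R_xlen_t j = 0; j < cols; ++j) {
      const double* xc = xp + j * C;
      double* yc = yp + j * C;
      for (int c = 0; c < C; ++c) {
        double a = xc[c] > 0 ? xc[c] : 0.0;
        yc[c] = scale[c] * a + shift[c];
      }
    }
    return List::create(_["y"] = y);
  }

  NumericVector xhat(no_init(total));
  double* hp = xhat.begin();
  if (kind == 0) {
    std::vector<double> s1(C, 0.0), s2(C, 0.0);
    R_xlen_t cols = static_cast<R_xlen_t>(N) * B;
    for (R_xlen_t j = 0; j < cols; ++j) {
      const double* xc = xp + j * C;
      for (int c = 0; c < C; ++c) {
        double a = xc[c] > 0 ? xc[c] : 0.0;
        s1[c] += a; s2[c] += a * a;
      }
    }
    double M = static_cast<double>(N) * B;
    NumericVector mu(C), inv(C);
    for (int c = 0; c < C; ++c) {
      mu[c] = s1[c] / M;
      double v = s2[c] / M - mu[c] * mu[c];
      if (v < 0) v = 0;
      inv[c] = 1.0 / std::sqrt(v + EPS);
    }
    for (R_xlen_t j = 0; j < cols; ++j) {
      const double* xc = xp + j * C;
      double* hc = hp + j * C;
      double* yc = yp + j * C;
      for (int c = 0; c < C; ++c) {
        double a = xc[c] > 0 ? xc[c] : 0.0;
        double h = (a - mu[c]) * inv[c];
        hc[c] = h;
        yc[c] = gp[c] * h + bp[c];
      }
    }
    NumericVector var(C);
    for (int c = 0; c < C; ++c) var[c] = 1.0 / (inv[c] * inv[c]) - EPS;
    return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                        _["inv"] = inv, _["var"] = var);
  }

  // kind 1: statistics per sample over C*N
  R_xlen_t CN = static_cast<R_xlen_t>(C) * N;
  NumericVector mu(B), inv(B);
  for (int b = 0; b < B; ++b) {
    const double* xb = xp + b * CN;
    double s1 = 0.0, s2 = 0.0;
    for (R_xlen_t i = 0; i < CN; ++i) {
      double a = xb[i] > 0 ? xb[i] : 0.0;
      s1 += a; s2 += a * a;
    }
    double m = s1 / CN;
    double v = s2 / CN - m * m;
    if (v < 0) v = 0;
    mu[b] = m;
    inv[b] = 1.0 / std::sqrt(v + EPS);
    double* hb = hp + b * CN;
    double* yb = yp + b * CN;
    for (int t = 0; t < N; ++t) {
      const double* xc = xb + static_cast<R_xlen_t>(t) * C;
      double* hc = hb + static_cast<R_xlen_t>(t) * C;
      double* yc = yb + static_cast<R_xlen_t>(t) * C;
      for (int c = 0; c < C; ++c) {
        double a = xc[c] > 0 ? xc[c] : 0.0;
        double h = (a - m) * inv[b];
        hc[c] = h;
        yc[c] = gp[c] * h + bp[c];
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu, _["inv"] = inv);
}

// [[Rcpp::export(name = ".relu_norm_bwd")]]
List relu_norm_bwd(NumericVector dy, NumericVector xhat, NumericVector mu,
                   NumericVector inv, NumericVector gamma,
                   int C, int N, int B, int kind) {
  R_xlen_t total = static_cast<R_xlen_t>(C) * N * B;
  NumericVector dx(no_init(total)), dgamma(C), dbeta(C);
  dx.attr("dim") = IntegerVector::create(C, N, B);
  const double* dyp = dy.begin();
  const double* hp = xhat.begin();
  const double* gp = gamma.begin();
  double* dxp = dx.begin();
  std::vector<double> dg(C, 0.0), db(C, 0.0);
  R_xlen_t cols = static_cast<R_xlen_t>(N) * B;
  for (R_xlen_t j = 0; j < cols; ++j) {
    const double* dyc = dyp + j * C;
    const double* hc = hp + j * C;
    for (int c = 0; c < C; ++c) {
      dg[c] += dyc[c] * hc[c];
      db[c] += dyc[c];
    }
  }
  for (int c = 0; c < C; ++c) { dgamma[c] = dg[c]; dbeta[c] = db[c]; }

  if (kind == 0) {
    double M = static_cast<double>(N) * B;
    std::vector<double> m1(C), m2(C), thr(C);
    for (int c = 0; c < C; ++c) {
      m1[c] = gp[c] * db[c] / M;
      m2[c] = gp[c] * dg[c] / M;
      thr[c] = -mu[c] * inv[c];   // xhat value of a zero activation
    }
    for (R_xlen_t j = 0; j < cols; ++j) {
      const double* dyc = dyp + j * C;
      const double* hc = hp + j * C;
      double* dxc = dxp + j * C;
      for (int c = 0; c < C; ++c) {
        double da = inv[c] * (dyc[c] * gp[c] - m1[c] - hc[c] * m2[c]);
        dxc[c] = hc[c] > thr[c] ? da : 0.0;
      }
    }
  } else {
    R_xlen_t CN = static_cast<R_xlen_t>(C) * N;
    for (int b = 0; b < B; ++b) {
      const double* dyb = dyp + b * CN;
      const double* hb = hp + b * CN;
      double s1 = 0.0, s2 = 0.0;
      for (int t = 0; t < N; ++t) {
        const double* dyc = dyb + static_cast<R_xlen_t>(t) * C;
        const double* hc = hb + static_cast<R_xlen_t>(t) * C;
        for (int c = 0; c < C; ++c) {
          double dxh = dyc[c] * gp[c];
          s1 += dxh; s2 += dxh * hc[c];
        }
      }
      double m1 = s1 / CN, m2 = s2 / CN;
      double thr = -mu[b] * inv[b];
      double* dxb = dxp + b * CN;
      for (int t = 0; t < N; ++t) {
        const double* dyc = dyb + static_cast<R_xlen_t>(t) * C;
        const double* hc = hb + static_cast<R_xlen_t>(t) * C;
        double* dxc = dxb + static_cast<R_xlen_t>(t) * C;
        for (int c = 0; c < C; ++c) {
          double da = inv[b] * (dyc[c] * gp[c] - m1 - hc[c] * m2);
          dxc[c] = hc[c] > thr ? da : 0.0;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ---- channel mixing as dgemm without reshape copies -------------------------
// y[f, t, b] = sum_c W[f, c] x[c, t, b] + bias[f]

// [[Rcpp::export(name = ".chmix_fwd")]]
NumericVector chmix_fwd_cpp(NumericVector x, NumericMatrix W, NumericVector bias,
                            int C, int N, int B) {
  int F = W.nrow();
  int M = N * B;
  NumericVector y(static_cast<R_xlen_t>(F) * M);
  const double one = 1.0, zero = 0.0;
  // y (F x M) = W (F x C) * x (C x M)
  F77_CALL(dgemm)("N", "N", &F, &M, &C, &one, W.begin(), &F,
                  x.begin(), &C, &zero, y.begin(), &F FCONE FCONE);
  double* yp = y.begin();
  const double* bp = bias.begin();
  for (R_xlen_t j = 0; j < M; ++j) {
    double* yc = yp + static_cast<R_xlen_t>(j) * F;
    for (int f = 0; f < F; ++f) yc[f] += bp[f];
  }
  y.attr("dim") = IntegerVector::create(F, N, B);
  return y;
}

// [[Rcpp::export(name = ".chmix_bwd")]]
List chmix_bwd_cpp(NumericVector dy, NumericVector x, NumericMatrix W,
                   int C, int N, int B) {
  int F = W.nrow();
  int M = N * B;
  NumericVector dx(static_cast<R_xlen_t>(C) * M);
  NumericMatrix dW(F, C);
  NumericVector db(F);
  const double one = 1.0, zero = 0.0;
  // dW (F x C) = dy (F x M) * x^T (M x C)
  F77_CALL(dgemm)("N", "T", &F, &C, &M, &one, dy.begin(), &F,
                  x.begin(), &C, &zero, dW.begin(), &F FCONE FCONE);
  // dx (C x M) = W^T (C x F) * dy (F x M)
  F77_CALL(dgemm)("T", "N", &C, &M, &F, &one, W.begin(), &F,
                  dy.begin(), &F, &zero, dx.begin(), &C FCONE FCONE);
  const double* dyp = dy.begin();
  double* dbp = db.begin();
  for (R_xlen_t j = 0; j < M; ++j) {
    const double* dyc = dyp + static_cast<R_xlen_t>(j) * F;
    for (int f = 0; f < F; ++f) dbp[f] += dyc[f];
  }
  dx.attr("dim") = IntegerVector::create(C, N, B);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// ---- non-overlapping average pooling ----------------------------------------

// [[Rcpp::export(name = ".avgpool_fwd")]]
NumericVector avgpool_fwd_cpp(NumericVector x, int C, int N, int B, int w) {
  int L = N / w;
  NumericVector y(static_cast<R_xlen_t>(C) * L * B);
  const double* xp = x.begin();
  double* yp = y.begin();
  double invw = 1.0 / w;
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < L; ++j) {
      const double* xs = xp + (static_cast<R_xlen_t>(b) * N + static_cast<R_xlen_t>(j) * w) * C;
      double* ys = yp + (static_cast<R_xlen_t>(b) * L + j) * C;
      for (int c = 0; c < C; ++c) ys[c] = 0.0;
      for (int t = 0; t < w; ++t) {
        const double* xt = xs + static_cast<R_xlen_t>(t) * C;
        for (int c = 0; c < C; ++c) ys[c] += xt[c];
      }
      for (int c = 0; c < C; ++c) ys[c] *= invw;
    }
  }
  y.attr("dim") = IntegerVector::create(C, L, B);
  return y;
}

// [[Rcpp::export(name = ".avgpool_bwd")]]
NumericVector avgpool_bwd_cpp(NumericVector dy, int C, int N, int B, int w) {
  int L = N / w;
  NumericVector dx(static_cast<R_xlen_t>(C) * N * B);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  double invw = 1.0 / w;
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < L; ++j) {
      const double* ds = dyp + (static_cast<R_xlen_t>(b) * L + j) * C;
      double* xs = dxp + (static_cast<R_xlen_t>(b) * N + static_cast<R_xlen_t>(j) * w) * C;
      for (int t = 0; t < w; ++t) {
        double* xt = xs + static_cast<R_xlen_t>(t) * C;
        for (int c = 0; c < C; ++c) xt[c] = ds[c] * invw;
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, N, B);
  return dx;
}
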