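#include <Rcpp.h>
#include <vector>
#include <cstring>

using namespace Rcpp;

// Depthwise temporal convolution (cross-correlation, "same" output length).
//
// Layouts, all column-major doubles:
//   x : C  x N x B   (input channels, time samples, batch)
//   w : K  x C*D     (one column of taps per output map; output map
//                     (c-1)*D + d reads input channel c)
//   y : C*D x N x B
//
// padL is the number of implicit zeros prepended in time; the total implicit
// padding is K - 1 so the temporal length is preserved (even K pads one more
// sample on the right than the left).
//
// The inner correlation loops are unrolled over four consecutive output
// samples with independent accumulators so the floating-point add chains
// pipeline; each (batch, channel) series is first gathered into a contiguous
// zero-padded buffer.

// Correlate a padded series (length N + K - 1) with taps w, writing N outputs
// into out with stride `ostride`.
static inline void corr1d(const double* xbuf, const double* w, int N, int K,
                          double* out, int ostride, double add) {
  int t = 0;
  for (; t + 3 < N; t += 4) {
    double a0 = add, a1 = add, a2 = add, a3 = add;
    const double* xs = xbuf + t;
    for (int k = 0; k < K; ++k) {
      double wk = w[k];
      a0 += wk * xs[k];
      a1 += wk * xs[k + 1];
      a2 += wk * xs[k + 2];
      a3 += wk * xs[k + 3];
    }
    out[static_cast<R_xlen_t>(t) * ostride] = a0;
    out[static_cast<R_xlen_t>(t + 1) * ostride] = a1;
    out[static_cast<R_xlen_t>(t + 2) * ostride] = a2;
    out[static_cast<R_xlen_t>(t + 3) * ostride] = a3;
  }
  for (; t < N; ++t) {
    double acc = add;
    const double* xs = xbuf + t;
    for (int k = 0; k < K; ++k) acc += w[k] * xs[k];
    out[static_cast<R_xlen_t>(t) * ostride] = acc;
  }
}

// [[Rcpp::export(name = ".dwconv_fwd")]]
NumericVector dwconv_fwd(NumericVector x, NumericVector w, NumericVector bias,
                         int C, int N, int B, int D, int padL) {
  int K = w.size() / (C * D);
  int Cout = C * D;
  NumericVector y(no_init(static_cast<R_xlen_t>(Cout) * N * B));
  std::vector<double> xbuf(N + K - 1, 0.0);
  const double* xp = x.begin();
  const double* wp = w.begin();  double* yp = y.begin();
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      std::fill(xbuf.begin(), xbuf.begin() + padL, 0.0);
      std::fill(xbuf.begin() + padL + N, xbuf.end(), 0.0);
      const double* xc = xp + (static_cast<R_xlen_t>(b) * N) * C + c;
      for (int t = 0; t < N; ++t) xbuf[padL + t] = xc[static_cast<R_xlen_t>(t) * C];
      for (int d = 0; d < D; ++d) {
        int co = c * D + d;
        corr1d(xbuf.data(), wp + static_cast<R_xlen_t>(co) * K, N, K,
               yp + (static_cast<R_xlen_t>(b) * N) * Cout + co, Cout, bias[co]);
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Cout, N, B);
  return y;
}

// Gradient w.r.t. the input: full correlation of dy with the reversed taps.
// [[Rcpp::export(name = ".dwconv_bwd_x")]]
NumericVector dwconv_bwd_x(NumericVector dy, NumericVector w,
                           int C, int N, int B, int D, int padL) {
  int K = w.size() / (C * D);
  int Cout = C * D;
  int padR = K - 1 - padL;
  NumericVector dx(no_init(static_cast<R_xlen_t>(C) * N * B));
  std::vector<double> dybuf(N + K - 1, 0.0);
  std::vector<double> wrev(K);
  std::vector<double> acc(N);
  const double* dyp = dy.begin();
  const double* wp = w.begin();
  double* dxp = dx.begin();
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int d = 0; d < D; ++d) {
        int co = c * D + d;
        const double* wk = wp + static_cast<R_xlen_t>(co) * K;
        for (int k = 0; k < K; ++k) wrev[k] = wk[K - 1 - k];
        std::fill(dybuf.begin(), dybuf.begin() + padR, 0.0);
        std::fill(dybuf.begin() + padR + N, dybuf.end(), 0.0);
        const double* dyo = dyp + (static_cast<R_xlen_t>(b) * N) * Cout + co;
        for (int t = 0; t < N; ++t) dybuf[padR + t] = dyo[static_cast<R_xlen_t>(t) * Cout];
        if (d == 0) {
          corr1d(dybuf.data(), wrev.data(), N, K, acc.data(), 1, 0.0);
        } else {
          // accumulate the second and later depth maps
          std::vector<double> tmp(N);
          corr1d(dybuf.data(), wrev.data(), N, K, tmp.data(), 1, 0.0);
          for (int t = 0; t < N; ++t) acc[t] += tmp[t];
        }
      }
      double* dxc = dxp + (static_cast<R_xlen_t>(b) * N) * C + c;
      for (int t = 0; t < N; ++t) dxc[static_cast<R_xlen_t>(t) * C] = acc[t];
    }
  }
  dx.attr("dim") = IntegerVector::create(C, N, B);
  return dx;
}

// Gradient w.r.t. the taps and biases:
// dW[k, co] = sum_{t,b} dy[co,t,b] * xpad[c, t+k]; db[co] = sum_{t,b} dy.
// [[Rcpp::export(name = ".dwconv_bwd_w")]]
List dwconv_bwd_w(NumericVector x, NumericVector dy,
                  int C, int N, int B, int D, int K, int padL) {
  int Cout = C * D;
  NumericMatrix dw(K, Cout);
  NumericVector db(Cout);
  std::vector<double> xbuf(N + K - 1, 0.0);
  std::vector<double> dybuf(N);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      std::fill(xbuf.begin(), xbuf.begin() + padL, 0.0);
      std::fill(xbuf.begin() + padL + N, xbuf.end(), 0.0);
      const double* xc = xp + (static_cast<R_xlen_t>(b) * N) * C + c;
      for (int t = 0; t < N; ++t) xbuf[padL + t] = xc[static_cast<R_xlen_t>(t) * C];
      for (int d = 0; d < D; ++d) {
        int co = c * D + d;
        const double* dyo = dyp + (static_cast<R_xlen_t>(b) * N) * Cout + co;
        double dbs = 0.0;
        for (int t = 0; t < N; ++t) {
          dybuf[t] = dyo[static_cast<R_xlen_t>(t) * Cout];
          dbs += dybuf[t];
        }
        db[co] += dbs;
        double* dwc = &dw(0, co);
        int k = 0;
        for (; k + 3 < K; k += 4) {
          double a0 = 0.0, a1 = 0.0, a2 = 0.0, a3 = 0.0;
          const double* xs = &xbuf[k];
          for (int t = 0; t < N; ++t) {
            double dt = dybuf[t];
            a0 += dt * xs[t];
            a1 += dt * xs[t + 1];
            a2 += dt * xs[t + 2];
            a3 += dt * xs[t + 3];
          }
          dwc[k] += a0; dwc[k + 1] += a1; dwc[k + 2] += a2; dwc[k + 3] += a3;
        }
        for (; k < K; ++k) {
          double acc = 0.0;
          const double* xs = &xbuf[k];
          for (int t = 0; t < N; ++t) acc += dybuf[t] * xs[t];
          dwc[k] += acc;
        }
      }
    }
  }
  return List::create(_["dW"] = dw, _["db"] = db);
}
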