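#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Tensor layout throughout: column-major [H, W, C, N] for activations and
// [k, k, Cin, Cout] for convolution kernels. Padding is asymmetric
// (top/left/bottom/right expressed via top/left offsets plus the padded
// size) so Keras-style 'same' padding at stride 2 is exact. Inputs are
// copied once into a zero-padded buffer so the accumulation loops are
// branch-free and contiguous in the fastest (height) index.

static inline int idx4(int a, int b, int c, int d, int A, int B, int C) {
  return a + A * (b + B * (c + C * d));
}

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, IntegerVector xd,
                            NumericVector w, IntegerVector wd,
                            NumericVector b, int stride,
                            int pt, int pl, int Ho, int Wo) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], F = wd[3];
  const int Hp = (Ho - 1) * stride + k, Wp = (Wo - 1) * stride + k;
  std::vector<double> xpad((size_t)Hp * Wp * C * N, 0.0);
  const double *xp = x.begin(), *wp = w.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < W; ++j) {
        if (j + pl >= Wp) continue;
        std::memcpy(&xpad[idx4(pt, j + pl, c, n, Hp, Wp, C)],
                    &xp[idx4(0, j, c, n, H, W, C)],
                    sizeof(double) * std::min(H, Hp - pt));
      }
  NumericVector y((R_xlen_t)Ho * Wo * F * N);
  double *yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f) {
      const double bf = b[f];
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = bf;
          for (int c = 0; c < C; ++c)
            for (int kw = 0; kw < k; ++kw) {
              const double *xq = &xpad[idx4(ho * stride, wo * stride + kw,
                                            c, n, Hp, Wp, C)];
              const double *wq = &wp[idx4(0, kw, c, f, k, k, C)];
              for (int kh = 0; kh < k; ++kh) acc += xq[kh] * wq[kh];
            }
          yp[idx4(ho, wo, f, n, Ho, Wo, F)] = acc;
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  return y;
}

// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, IntegerVector xd,
                   NumericVector w, IntegerVector wd,
                   NumericVector dy, int stride,
                   int pt, int pl, int Ho, int Wo,
                   bool want_dx, bool want_dw) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], F = wd[3];
  const int Hp = (Ho - 1) * stride + k, Wp = (Wo - 1) * stride + k;
  const size_t padsz = (size_t)Hp * Wp * C * N;
  std::vector<double> xpad(padsz, 0.0), dxpad;
  const double *xp = x.begin(), *wp = w.begin(), *dyp = dy.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < W; ++j) {
        if (j + pl >= Wp) continue;
        std::memcpy(&xpad[idx4(pt, j + pl, c, n, Hp, Wp, C)],
                    &xp[idx4(0, j, c, n, H, W, C)],
                    sizeof(double) * std::min(H, Hp - pt));
      }
  if (want_dx) dxpad.assign(padsz, 0.0);
  NumericVector dw(want_dw ? w.size() : 0);
  NumericVector db(F);
  double *dwp = dw.begin();
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f) {
      double dbf = 0.0;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = dyp[idx4(ho, wo, f, n, Ho, Wo, F)];
          if (g == 0.0) continue;
          dbf += g;
          for (int c = 0; c < C; ++c)
            for (int kw = 0; kw < k; ++kw) {
              const size_t xi = idx4(ho * stride, wo * stride + kw, c, n,
                                     Hp, Wp, C);
              const int wi = idx4(0, kw, c, f, k, k, C);
              if (want_dx) {
                double *dq = &dxpad[xi];
                const double *wq = &wp[wi];
                for (int kh = 0; kh < k; ++kh) dq[kh] += g * wq[kh];
              }
              if (want_dw) {
                const double *xq = &xpad[xi];
                double *dwq = &dwp[wi];
                for (int kh = 0; kh < k; ++kh) dwq[kh] += g * xq[kh];
              }
            }
        }
      db[f] += dbf;
    }
  NumericVector dx(want_dx ? x.size() : 0);
  if (want_dx) {
    double *dxp = dx.begin();
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c)
        for (int j = 0; j < W; ++j) {
          if (j + pl >= Wp) continue;
          const double *src = &dxpad[idx4(pt, j + pl, c, n, Hp, Wp, C)];
          double *dst = &dxp[idx4(0, j, c, n, H, W, C)];
          const int hh = std::min(H, Hp - pt);
          for (int i = 0; i < hh; ++i) dst[i] += src[i];
        }
    dx.attr("dim") = xd;
  }
  if (want_dw) dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns pooled values and the 1-based linear
// argmax index into x (used for routing gradients and tangents).
// [[Rcpp::export]]
List maxpool2_fw_cpp(NumericVector x, IntegerVector xd) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector am(y.size());
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf; int bi = -1;
          for (int dw_ = 0; dw_ < 2; ++dw_)
            for (int dh = 0; dh < 2; ++dh) {
              const int xi = idx4(2 * ho + dh, 2 * wo + dw_, c, n, H, W, C);
              if (x[xi] > best) { best = x[xi]; bi = xi; }
            }
          const int yi = idx4(ho, wo, c, n, Ho, Wo, C);
          y[yi] = best;
          am[yi] = bi + 1;
        }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw_cpp(NumericVector dy, IntegerVector argmax,
                              IntegerVector xd) {
  NumericVector dx((R_xlen_t)xd[0] * xd[1] * xd[2] * xd[3]);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[argmax[i] - 1] += dy[i];
  dx.attr("dim") = xd;
  return dx;
}
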