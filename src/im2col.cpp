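#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

// "Same"-padded k x k convolution kernels for flat activation matrices.
//
// Activations are (h*w*n) x C matrices: rows ordered pixel-within-sample
// fastest (column-major over each h x w grid), then sample. The im2col
// patch matrix is built per sample (npix x k2*C, a few MB, cache
// resident) and multiplied with BLAS dgemm, so the k^2-fold expanded
// data is never materialized for the whole batch. Within a channel
// block, tap kk = dj*k + di (di fastest) multiplies the row of a weight
// matrix laid out as the col-major flattening of a (k, k, cin) block.

// build the patch matrix of one sample
// src: pointer to this sample's channel-0 block; channels strided by chan_stride
static void patch_matrix(const double* src, size_t chan_stride,
                         int h, int w, int cin, int k,
                         std::vector<double>& p, std::vector<double>& m) {
  const int pad = (k - 1) / 2;
  const int hp = h + 2 * pad;
  const int npix = h * w, k2 = k * k;
  const size_t plane = (size_t)hp * (w + 2 * pad);
  for (int c = 0; c < cin; ++c) {
    std::fill(p.begin(), p.end(), 0.0);
    const double* ac = src + (size_t)c * chan_stride;
    for (int j = 0; j < w; ++j) {
      std::copy(ac + (size_t)j * h, ac + (size_t)(j + 1) * h,
                &p[(size_t)(j + pad) * hp + pad]);
    }
    for (int kk = 0; kk < k2; ++kk) {
      const int di = kk % k, dj = kk / k;
      double* mc = &m[((size_t)c * k2 + kk) * npix];
      for (int j = 0; j < w; ++j) {
        const double* sp = &p[(size_t)(j + dj) * hp + di];
        std::copy(sp, sp + h, mc + (size_t)j * h);
      }
    }
  }
  (void)plane;
}

// [[Rcpp::export]]
NumericMatrix conv_fwd_cpp(const NumericMatrix& a, const NumericMatrix& W,
                           const NumericVector& bias, int h, int w, int n, int k) {
  const int npix = h * w, k2 = k * k;
  const int cin = a.ncol(), cout = W.ncol();
  const int kdim = k2 * cin;
  const int pad = (k - 1) / 2;
  const size_t rows = (size_t)npix * n;
  NumericMatrix y(rows, cout);
  std::vector<double> p((size_t)(h + 2 * pad) * (w + 2 * pad));
  std::vector<double> m((size_t)npix * kdim);
  const double one = 1.0, zero = 0.0;
  const int ldy = (int)rows;
  for (int s = 0; s < n; ++s) {
    patch_matrix(&a[(size_t)s * npix], rows, h, w, cin, k, p, m);
    F77_CALL(dgemm)("N", "N", &npix, &cout, &kdim, &one, m.data(), &npix,
                    REAL(W), &kdim, &zero, REAL(y) + (size_t)s * npix, &ldy
                    FCONE FCONE);
  }
  for (int c = 0; c < cout; ++c) {
    const double b = bias[c];
    if (b != 0.0) {
      double* yc = REAL(y) + (size_t)c * rows;
      for (size_t i = 0; i < rows; ++i) yc[i] += b;
    }
  }
  return y;
}

// gradients of the same convolution: dW = im2col(a)^T dy (if need_dw),
// dx = im2col(dy) %*% Wflip (if need_dx); db is cheap in R.
// [[Rcpp::export]]
List conv_bwd_cpp(const NumericMatrix& a, const NumericMatrix& dy,
                  const NumericMatrix& Wflip, int h, int w, int n, int k,
                  bool need_dw, bool need_dx) {
  const int npix = h * w, k2 = k * k;
  const int cin = a.ncol(), cout = dy.ncol();
  const int pad = (k - 1) / 2;
  const size_t rows = (size_t)npix * n;
  const int ldr = (int)rows;
  const double one = 1.0, zero = 0.0;
  std::vector<double> p((size_t)(h + 2 * pad) * (w + 2 * pad));
  NumericMatrix dW, dx;
  if (need_dw) {
    const int kdim = k2 * cin;
    dW = NumericMatrix(kdim, cout);
    std::vector<double> m((size_t)npix * kdim);
    for (int s = 0; s < n; ++s) {
      patch_matrix(&a[(size_t)s * npix], rows, h, w, cin, k, p, m);
      F77_CALL(dgemm)("T", "N", &kdim, &cout, &npix, &one, m.data(), &npix,
                      REAL(dy) + (size_t)s * npix, &ldr, &one, REAL(dW), &kdim
                      FCONE FCONE);
    }
  }
  if (need_dx) {
    const int kdim = k2 * cout; // patches of dy
    dx = NumericMatrix(rows, cin);
    std::vector<double> m((size_t)npix * kdim);
    for (int s = 0; s < n; ++s) {
      patch_matrix(&dy[(size_t)s * npix], rows, h, w, cout, k, p, m);
      F77_CALL(dgemm)("N", "N", &npix, &cin, &kdim, &one, m.data(), &npix,
                      REAL(Wflip), &kdim, &zero, REAL(dx) + (size_t)s * npix, &ldr
                      FCONE FCONE);
    }
  }
  return List::create(_["dW"] = need_dw ? (SEXP)dW : R_NilValue,
                      _["dx"] = need_dx ? (SEXP)dx : R_NilValue);
}
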