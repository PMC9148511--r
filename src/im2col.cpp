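#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Activations for a mini-batch are stored as a dense matrix with one row per
// pixel and one column per channel.  Row order is height-fastest:
//   row(h, w, n) = h + H*w + H*W*n   (0-based)
// so that for a fixed (w, n) a run over h is contiguous in memory and the
// im2col gather reduces to block copies of length <= H.
//
// Patch-column order matches the flattening of an R kernel array with
// dim c(k, k, C_in, C_out):  col(ki, kj, c) = ki + k*kj + k*k*c,
// hence conv output = im2col(X) %*% matrix(W, k*k*C_in, C_out).

// [[Rcpp::export]]
NumericMatrix im2col_dilated(const NumericMatrix& X, int H, int W, int N,
                             int k, int r) {
  const int C = X.ncol();
  const int npix = H * W * N;
  if (X.nrow() != npix) stop("X has %d rows; expected H*W*N = %d", X.nrow(), npix);
  if (k < 1 || k % 2 == 0) stop("kernel size must be odd and positive");
  if (r < 1) stop("dilation rate must be a positive integer");
  const int half = (k - 1) / 2;
  NumericMatrix P(npix, k * k * C);
  const double* xp = X.begin();
  double* pp = P.begin();

  for (int c = 0; c < C; ++c) {
    const double* xcol = xp + (size_t)c * npix;
    for (int kj = 0; kj < k; ++kj) {
      const int dx = (kj - half) * r;
      for (int ki = 0; ki < k; ++ki) {
        const int dy = (ki - half) * r;
        double* pcol = pp + (size_t)(ki + k * kj + k * k * c) * npix;
        // valid output-h range so that h + dy lies in [0, H)
        const int h0 = dy < 0 ? -dy : 0;
        const int h1 = dy > 0 ? H - dy : H;  // exclusive
        const int len = h1 - h0;
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < W; ++w) {
            const int ws = w + dx;
            double* dst = pcol + (size_t)(H * (w + W * n));
            if (ws < 0 || ws >= W || len <= 0) continue;  // zero padding
            const double* src = xcol + (size_t)(H * (ws + W * n));
            std::memcpy(dst + h0, src + h0 + dy, (size_t)len * sizeof(double));
          }
        }
      }
    }
  }
  return P;
}

// Adjoint of im2col_dilated: scatter-adds patch-matrix gradients back onto
// the input grid.  Used for the input-gradient half of convolution backprop.

// [[Rcpp::export]]
NumericMatrix col2im_dilated(const NumericMatrix& P, int H, int W, int N,
                             int C, int k, int r) {
  const int npix = H * W * N;
  if (P.nrow() != npix) stop("P has %d rows; expected H*W*N = %d", P.nrow(), npix);
  if (P.ncol() != k * k * C) stop("P has %d cols; expected k*k*C = %d", P.ncol(), k * k * C);
  const int half = (k - 1) / 2;
  NumericMatrix X(npix, C);
  const double* pp = P.begin();
  double* xp = X.begin();

  for (int c = 0; c < C; ++c) {
    double* xcol = xp + (size_t)c * npix;
    for (int kj = 0; kj < k; ++kj) {
      const int dx = (kj - half) * r;
      for (int ki = 0; ki < k; ++ki) {
        const int dy = (ki - half) * r;
        const double* pcol = pp + (size_t)(ki + k * kj + k * k * c) * npix;
        const int h0 = dy < 0 ? -dy : 0;
        const int h1 = dy > 0 ? H - dy : H;
        const int len = h1 - h0;
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < W; ++w) {
            const int ws = w + dx;
            if (ws < 0 || ws >= W || len <= 0) continue;
            const double* src = pcol + (size_t)(H * (w + W * n));
            double* dst = xcol + (size_t)(H * (ws + W * n));
            for (int h = h0; h < h1; ++h) dst[h + dy] += src[h];
          }
        }
      }
    }
  }
  return X;
}
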