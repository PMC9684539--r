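// Low-level primitives for the convolutional training engine.
//
// Activations are stored as C x (H*W*N) matrices, column index
// (n-1)*H*W + (w-1)*H + h (pixel-major within image, image-major across the
// batch).  im2col rows are grouped by channel: row = (c-1)*kh*kw +
// (kw_i-1)*kh + kh_i, which keeps each channel's taps contiguous for the
// depthwise convolutions.  Convolution itself is a GEMM done in R via BLAS.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericMatrix& A, int H, int W, int N,
                         int kh, int kw, int stride, int pad) {
  const int C = A.nrow();
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericMatrix out(kh * kw * C, Ho * Wo * N);
  const double* a = A.begin();
  double* o = out.begin();
  const int orow = kh * kw * C;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t ocol = (R_xlen_t)n * Ho * Wo + (R_xlen_t)wo * Ho + ho;
        const int h0 = ho * stride - pad, w0 = wo * stride - pad;
        for (int kwi = 0; kwi < kw; ++kwi) {
          const int ws = w0 + kwi;
          if (ws < 0 || ws >= W) continue;
          for (int khi = 0; khi < kh; ++khi) {
            const int hs = h0 + khi;
            if (hs < 0 || hs >= H) continue;
            const R_xlen_t icol = (R_xlen_t)n * H * W + (R_xlen_t)ws * H + hs;
            const double* ain = a + icol * C;
            double* oout = o + ocol * orow + (kwi * kh + khi);
            for (int c = 0; c < C; ++c)
              oout[(R_xlen_t)c * kh * kw] = ain[c];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add column gradients back onto the input grid.
// [[Rcpp::export]]
NumericMatrix col2im_cpp(const NumericMatrix& cols, int C, int H, int W,
                         int N, int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericMatrix out(C, (R_xlen_t)H * W * N);
  const double* cl = cols.begin();
  double* o = out.begin();
  const int crow = cols.nrow();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t ccol = (R_xlen_t)n * Ho * Wo + (R_xlen_t)wo * Ho + ho;
        const int h0 = ho * stride - pad, w0 = wo * stride - pad;
        for (int kwi = 0; kwi < kw; ++kwi) {
          const int ws = w0 + kwi;
          if (ws < 0 || ws >= W) continue;
          for (int khi = 0; khi < kh; ++khi) {
            const int hs = h0 + khi;
            if (hs < 0 || hs >= H) continue;
            const R_xlen_t icol = (R_xlen_t)n * H * W + (R_xlen_t)ws * H + hs;
            double* oout = o + icol * C;
            const double* cin = cl + ccol * crow + (kwi * kh + khi);
            for (int c = 0; c < C; ++c)
              oout[c] += cin[(R_xlen_t)c * kh * kw];
          }
        }
      }
    }
  }
  return out;
}

// Max pooling with argmax bookkeeping (input column indices, 1-based) for
// the backward pass.  Zero padding; padded positions never win the max.
// [[Rcpp::export]]
List maxpool_cpp(const NumericMatrix& A, int H, int W, int N,
                 int k, int stride, int pad) {
  const int C = A.nrow();
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(C, (R_xlen_t)Ho * Wo * N);
  IntegerMatrix arg(C, (R_xlen_t)Ho * Wo * N);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t ocol = (R_xlen_t)n * Ho * Wo + (R_xlen_t)wo * Ho + ho;
        const int h0 = ho * stride - pad, w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf; int bestcol = -1;
          for (int kwi = 0; kwi < k; ++kwi) {
            const int ws = w0 + kwi;
            if (ws < 0 || ws >= W) continue;
            for (int khi = 0; khi < k; ++khi) {
              const int hs = h0 + khi;
              if (hs < 0 || hs >= H) continue;
              const R_xlen_t icol = (R_xlen_t)n * H * W + (R_xlen_t)ws * H + hs;
              const double v = A(c, icol);
              if (v > best) { best = v; bestcol = (int)icol; }
            }
          }
          if (bestcol < 0) { best = 0.0; bestcol = 0; }
          out(c, ocol) = best;
          arg(c, ocol) = bestcol + 1;   // 1-based for R
        }
      }
    }
  }
  return List::create(Named("out") = out, Named("argmax") = arg);
}

// [[Rcpp::export]]
NumericMatrix maxpool_back_cpp(const NumericMatrix& dOut,
                               const IntegerMatrix& arg, int ncolIn) {
  const int C = dOut.nrow();
  NumericMatrix dX(C, ncolIn);
  for (R_xlen_t j = 0; j < dOut.ncol(); ++j)
    for (int c = 0; c < C; ++c)
      dX(c, arg(c, j) - 1) += dOut(c, j);
  return dX;
}
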