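#include <Rcpp.h>
using namespace Rcpp;

// Patch-matrix (im2col) layout, all 0-based here:
//   input x is an (H, W, C) array in R's column-major order:
//     x[h + w*H + c*H*W]
//   output has one column per output pixel, column index p = oh + ow*Hout
//   (column-major over the output grid), and one row per kernel tap,
//   row index q = kh + kw*K + c*K*K.
// Zero padding outside the input. Stride and dilation as in standard
// convolution arithmetic: Hout = (H + 2*pad - eff)/stride + 1 with
// eff = (K-1)*dilation + 1.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int K, int stride, int pad, int dilation) {
  const int eff = (K - 1) * dilation + 1;
  const int Hout = (H + 2 * pad - eff) / stride + 1;
  const int Wout = (W + 2 * pad - eff) / stride + 1;
  NumericMatrix cols(C * K * K, Hout * Wout);
  double *out = cols.begin();
  const double *in = x.begin();
  for (int ow = 0; ow < Wout; ++ow) {
    for (int oh = 0; oh < Hout; ++oh) {
      const int p = oh + ow * Hout;
      double *colp = out + (R_xlen_t)p * (C * K * K);
      for (int c = 0; c < C; ++c) {
        const double *plane = in + (R_xlen_t)c * H * W;
        for (int kw = 0; kw < K; ++kw) {
          const int w = ow * stride - pad + kw * dilation;
          for (int kh = 0; kh < K; ++kh) {
            const int h = oh * stride - pad + kh * dilation;
            const int q = kh + kw * K + c * K * K;
            colp[q] = (h >= 0 && h < H && w >= 0 && w < W)
                        ? plane[h + (R_xlen_t)w * H] : 0.0;
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col_cpp, taking the gradient in transposed layout
// (one ROW per output pixel, one column per kernel tap) so the caller can
// produce it with a single BLAS call and no large transpose.
// [[Rcpp::export]]
NumericVector col2im_t_cpp(NumericMatrix cols_t, int H, int W, int C,
                           int K, int stride, int pad, int dilation) {
  const int eff = (K - 1) * dilation + 1;
  const int Hout = (H + 2 * pad - eff) / stride + 1;
  const int Wout = (W + 2 * pad - eff) / stride + 1;
  const R_xlen_t P = (R_xlen_t)Hout * Wout;
  NumericVector gx((R_xlen_t)H * W * C);
  double *out = gx.begin();
  const double *in = cols_t.begin();
  for (int c = 0; c < C; ++c) {
    double *plane = out + (R_xlen_t)c * H * W;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const int q = kh + kw * K + c * K * K;
        const double *col = in + (R_xlen_t)q * P;  // column q, P entries
        for (int ow = 0; ow < Wout; ++ow) {
          const int w = ow * stride - pad + kw * dilation;
          if (w < 0 || w >= W) continue;
          for (int oh = 0; oh < Hout; ++oh) {
            const int h = oh * stride - pad + kh * dilation;
            if (h < 0 || h >= H) continue;
            plane[h + (R_xlen_t)w * H] += col[oh + (R_xlen_t)ow * Hout];
          }
        }
      }
    }
  }
  return gx;
}
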