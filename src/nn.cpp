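// Minimal convolution primitives for the conditional adversarial denoiser:
// im2col/col2im re-expression of 2-D convolution so that forward and both
// backward passes reduce to one BLAS gemm each (via Armadillo). Patches are
// laid out as (pixels x taps) so every inner loop walks contiguous memory.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// x: (H, W, C) cube -> (Ho*Wo) x (kh*kw*C) patch matrix, zero padding `pad`.
static arma::mat im2col_t(const arma::cube &x, int kh, int kw, int stride,
                          int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  arma::mat cols((size_t)Ho * Wo, kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat &sl = x.slice(c);
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const int kcol = c * kh * kw + j * kh + i;
        double *dst = cols.colptr(kcol);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wsrc = wo * stride + j - pad;
          if (wsrc < 0 || wsrc >= W) continue;
          const double *src = sl.colptr(wsrc);
          const int h0 = std::max(0, (pad - i + stride - 1) / stride);
          for (int ho = h0; ho < Ho; ++ho) {
            const int hsrc = ho * stride + i - pad;
            if (hsrc >= H) break;
            dst[(size_t)wo * Ho + ho] = src[hsrc];
          }
        }
      }
  }
  return cols;
}

// adjoint: scatter-add (Ho*Wo) x (kh*kw*C) patch gradients into the input
static arma::cube col2im_t(const arma::mat &cols, int H, int W, int C, int kh,
                           int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat &sl = x.slice(c);
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const int kcol = c * kh * kw + j * kh + i;
        const double *src = cols.colptr(kcol);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wsrc = wo * stride + j - pad;
          if (wsrc < 0 || wsrc >= W) continue;
          double *dst = sl.colptr(wsrc);
          const int h0 = std::max(0, (pad - i + stride - 1) / stride);
          for (int ho = h0; ho < Ho; ++ho) {
            const int hsrc = ho * stride + i - pad;
            if (hsrc >= H) break;
            dst[hsrc] += src[(size_t)wo * Ho + ho];
          }
        }
      }
  }
  return x;
}

// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::cube &x, int kh, int kw, int stride,
                     int pad) {
  return im2col_t(x, kh, kw, stride, pad);
}

// Convolution forward: weights W is (Cout) x (kh*kw*Cin). Returns (Ho,Wo,Cout).
// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube &x, const arma::mat &Wt,
                        const arma::vec &b, int kh, int kw, int stride,
                        int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  arma::mat cols = im2col_t(x, kh, kw, stride, pad);
  arma::mat y = cols * Wt.t();           // (Ho*Wo) x Cout
  y.each_row() += b.t();
  arma::cube out(Ho, Wo, Wt.n_rows);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// Convolution backward. gy: (Ho,Wo,Cout). Returns list(gx, gW, gb).
// [[Rcpp::export]]
List cpp_conv_bwd(const arma::cube &x, const arma::mat &Wt, const arma::cube &gy,
                  int kh, int kw, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = gy.n_rows, Wo = gy.n_cols, Cout = gy.n_slices;
  arma::mat gmat((size_t)Ho * Wo, Cout);
  std::memcpy(gmat.memptr(), gy.memptr(), sizeof(double) * gy.n_elem);
  arma::mat cols = im2col_t(x, kh, kw, stride, pad);
  arma::mat gW = gmat.t() * cols;        // Cout x (kh*kw*C)
  arma::vec gb = arma::sum(gmat, 0).t();
  arma::mat gcols = gmat * Wt;           // (Ho*Wo) x (kh*kw*C)
  arma::cube gx = col2im_t(gcols, H, W, C, kh, kw, stride, pad);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}
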