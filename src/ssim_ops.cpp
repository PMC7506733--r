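// Separable Gaussian window primitives for SSIM / MS-SSIM and their
// adjoints. Statistics windows use 'valid' correlation (output shrinks by
// the window size minus one); the adjoint of valid correlation with a
// symmetric kernel is full convolution, used by the analytic MS-SSIM
// gradient. 2x2 average pooling implements the dyadic scale pyramid.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix sep_corr_valid(NumericMatrix x, NumericVector g) {
  const int H = x.nrow(), W = x.ncol(), L = g.size();
  if (H < L || W < L) stop("image smaller than window");
  const int Ho = H - L + 1, Wo = W - L + 1;
  NumericMatrix tmp(Ho, W);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < Ho; ++h) {
      double s = 0.0;
      for (int t = 0; t < L; ++t) s += g[t] * x(h + t, w);
      tmp(h, w) = s;
    }
  NumericMatrix y(Ho, Wo);
  for (int w = 0; w < Wo; ++w)
    for (int h = 0; h < Ho; ++h) {
      double s = 0.0;
      for (int t = 0; t < L; ++t) s += g[t] * tmp(h, w + t);
      y(h, w) = s;
    }
  return y;
}

// [[Rcpp::export]]
NumericMatrix sep_conv_full(NumericMatrix x, NumericVector g) {
  const int H = x.nrow(), W = x.ncol(), L = g.size();
  const int Ho = H + L - 1, Wo = W + L - 1;
  NumericMatrix tmp(Ho, W);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      const double v = x(h, w);
      if (v == 0.0) continue;
      for (int t = 0; t < L; ++t) tmp(h + t, w) += g[t] * v;
    }
  NumericMatrix y(Ho, Wo);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < Ho; ++h) {
      const double v = tmp(h, w);
      if (v == 0.0) continue;
      for (int t = 0; t < L; ++t) y(h, w + t) += g[t] * v;
    }
  return y;
}

// [[Rcpp::export]]
NumericMatrix avgpool2_m(NumericMatrix x) {
  const int Ho = x.nrow() / 2, Wo = x.ncol() / 2;
  NumericMatrix y(Ho, Wo);
  for (int w = 0; w < Wo; ++w)
    for (int h = 0; h < Ho; ++h)
      y(h, w) = 0.25 * (x(2 * h, 2 * w) + x(2 * h + 1, 2 * w) +
                        x(2 * h, 2 * w + 1) + x(2 * h + 1, 2 * w + 1));
  return y;
}

// [[Rcpp::export]]
NumericMatrix avgpool2_adj(NumericMatrix dy, int H, int W) {
  NumericMatrix dx(H, W);
  const int Ho = dy.nrow(), Wo = dy.ncol();
  for (int w = 0; w < Wo; ++w)
    for (int h = 0; h < Ho; ++h) {
      const double v = 0.25 * dy(h, w);
      dx(2 * h, 2 * w) = v;
      dx(2 * h + 1, 2 * w) = v;
      dx(2 * h, 2 * w + 1) = v;
      dx(2 * h + 1, 2 * w + 1) = v;
    }
  return dx;
}
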