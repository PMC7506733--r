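// Classical despeckling baselines that have no ready-made R implementation
// in this package's dependency set: non-local means and the bilateral
// filter. Borders are handled by renormalising weights over in-bounds
// pixels (no padding), so constant images are exact fixed points.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix nlm_cpp(NumericMatrix x, int patch, int window, double h,
                      double sigma) {
  const int H = x.nrow(), W = x.ncol();
  const int pr = patch / 2, wr = window / 2;
  const double h2 = h * h;
  const double off = 2.0 * sigma * sigma;  // expected patch distance of pure noise
  NumericMatrix y(H, W);
  // symmetric (reflect) padding for patch comparisons
  const int Hp = H + 2 * pr, Wp = W + 2 * pr;
  std::vector<double> pad((size_t)Hp * Wp);
  auto refl = [](int i, int n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
    return i;
  };
  for (int w = 0; w < Wp; ++w)
    for (int hh = 0; hh < Hp; ++hh)
      pad[(size_t)hh + (size_t)Hp * w] = x(refl(hh - pr, H), refl(w - pr, W));
  const double npx = (double)patch * patch;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double wsum = 0.0, vsum = 0.0;
      for (int dc = -wr; dc <= wr; ++dc) {
        const int c2 = c + dc;
        if (c2 < 0 || c2 >= W) continue;
        for (int dr = -wr; dr <= wr; ++dr) {
          const int r2 = r + dr;
          if (r2 < 0 || r2 >= H) continue;
          double d2 = 0.0;
          for (int pc = 0; pc < patch; ++pc) {
            const double* a = &pad[(size_t)r + (size_t)Hp * (c + pc)];
            const double* b = &pad[(size_t)r2 + (size_t)Hp * (c2 + pc)];
            for (int pr2 = 0; pr2 < patch; ++pr2) {
              const double dd = a[pr2] - b[pr2];
              d2 += dd * dd;
            }
          }
          const double dbar = d2 / npx - off;
          const double wgt = std::exp(-(dbar > 0.0 ? dbar : 0.0) / h2);
          wsum += wgt;
          vsum += wgt * x(r2, c2);
        }
      }
      y(r, c) = vsum / wsum;
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericMatrix bilateral_cpp(NumericMatrix x, double sigma_s, double sigma_r) {
  const int H = x.nrow(), W = x.ncol();
  const int rad = (int)std::ceil(3.0 * sigma_s);
  const double is2 = 1.0 / (2.0 * sigma_s * sigma_s);
  const double ir2 = 1.0 / (2.0 * sigma_r * sigma_r);
  NumericMatrix y(H, W);
  std::vector<double> gs(2 * rad + 1);
  for (int t = -rad; t <= rad; ++t) gs[t + rad] = std::exp(-t * t * is2);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      const double v0 = x(r, c);
      double wsum = 0.0, vsum = 0.0;
      for (int dc = -rad; dc <= rad; ++dc) {
        const int c2 = c + dc;
        if (c2 < 0 || c2 >= W) continue;
        for (int dr = -rad; dr <= rad; ++dr) {
          const int r2 = r + dr;
          if (r2 < 0 || r2 >= H) continue;
          const double dv = x(r2, c2) - v0;
          const double wgt = gs[dr + rad] * gs[dc + rad] * std::exp(-dv * dv * ir2);
          wsum += wgt;
          vsum += wgt * x(r2, c2);
        }
      }
      y(r, c) = vsum / wsum;
    }
  return y;
}
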