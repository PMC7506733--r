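// Native compute kernels for the residual U-net: same-padded convolution,
// 2x2 max pooling, 2x2 stride-2 transpose convolution and batch
// normalisation, each with its analytic backward pass. Layout throughout:
// activations (H, W, C, N) column-major, conv weights (kh, kw, Cin, Cout).
// Convolutions are lowered to GEMM via im2col with the pixel index as the
// row dimension, so the GEMM output writes straight into the (H*W, Cout)
// slab of the output array without a transpose.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline arma::mat im2col_same(const double* x, int H, int W, int Cin,
                                    int kh, int kw) {
  const int ph = kh / 2, pw = kw / 2;
  arma::mat col(H * W, (arma::uword)kh * kw * Cin);
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (arma::uword)ci * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int k = i + kh * j + kh * kw * ci;
        double* dst = col.colptr(k);
        const int di = i - ph, dj = j - pw;
        for (int w = 0; w < W; ++w) {
          const int ws = w + dj;
          double* dcol = dst + (arma::uword)w * H;
          if (ws < 0 || ws >= W) {
            std::fill(dcol, dcol + H, 0.0);
            continue;
          }
          const double* src = xc + (arma::uword)ws * H;
          for (int h = 0; h < H; ++h) {
            const int hs = h + di;
            dcol[h] = (hs < 0 || hs >= H) ? 0.0 : src[hs];
          }
        }
      }
    }
  }
  return col;
}

static inline void col2im_same_add(const arma::mat& dcol, double* dx, int H,
                                   int W, int Cin, int kh, int kw) {
  const int ph = kh / 2, pw = kw / 2;
  for (int ci = 0; ci < Cin; ++ci) {
    double* xc = dx + (arma::uword)ci * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int k = i + kh * j + kh * kw * ci;
        const double* src = dcol.colptr(k);
        const int di = i - ph, dj = j - pw;
        for (int w = 0; w < W; ++w) {
          const int ws = w + dj;
          if (ws < 0 || ws >= W) continue;
          double* xcol = xc + (arma::uword)ws * H;
          const double* scol = src + (arma::uword)w * H;
          for (int h = 0; h < H; ++h) {
            const int hs = h + di;
            if (hs >= 0 && hs < H) xcol[hs] += scol[h];
          }
        }
      }
    }
  }
}

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  return d;
}

// [[Rcpp::export]]
NumericVector conv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = dims4(x), dw = dims4(w);
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[3];
  if (dw[2] != Cin) stop("weight Cin mismatch");
  const arma::uword K = (arma::uword)kh * kw * Cin;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  NumericVector y = alloc4(H, W, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col_same(x.begin() + (arma::uword)n * H * W * Cin, H, W,
                                Cin, kh, kw);
    arma::mat Y(y.begin() + (arma::uword)n * H * W * Cout, (arma::uword)H * W,
                Cout, false, true);
    Y = col * Wm;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector dx_ = dims4(x), dw_ = dims4(w);
  const int H = dx_[0], W = dx_[1], Cin = dx_[2], N = dx_[3];
  const int kh = dw_[0], kw = dw_[1], Cout = dw_[3];
  const arma::uword K = (arma::uword)kh * kw * Cin;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector dx = alloc4(H, W, Cin, N);
  NumericVector dw = alloc4(kh, kw, Cin, Cout);
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col_same(x.begin() + (arma::uword)n * H * W * Cin, H, W,
                                Cin, kh, kw);
    arma::mat dY(const_cast<double*>(dy.begin()) + (arma::uword)n * H * W * Cout,
                 (arma::uword)H * W, Cout, false, true);
    dWm += col.t() * dY;
    dbv += arma::sum(dY, 0).t();
    arma::mat dcol = dY * Wm.t();
    col2im_same_add(dcol, dx.begin() + (arma::uword)n * H * W * Cin, H, W, Cin,
                    kh, kw);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool_fwd(NumericVector x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("maxpool needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N);  // linear offset into (H, W)
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + ((arma::uword)c + (arma::uword)C * n) * H * W;
      double* ys = y.begin() + ((arma::uword)c + (arma::uword)C * n) * Ho * Wo;
      int* is = idx.begin() + ((arma::uword)c + (arma::uword)C * n) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = 2 * ho, w0 = 2 * wo;
          int best = h0 + H * w0;
          double bv = xs[best];
          const int cand[3] = {h0 + 1 + H * w0, h0 + H * (w0 + 1),
                               h0 + 1 + H * (w0 + 1)};
          for (int t = 0; t < 3; ++t)
            if (xs[cand[t]] > bv) { bv = xs[cand[t]]; best = cand[t]; }
          ys[ho + Ho * wo] = bv;
          is[ho + Ho * wo] = best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd(IntegerVector idx, NumericVector dy, int H, int W) {
  IntegerVector d = dims4(dy);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xs = dx.begin() + ((arma::uword)c + (arma::uword)C * n) * H * W;
      const double* ys = dy.begin() + ((arma::uword)c + (arma::uword)C * n) * Ho * Wo;
      const int* is = idx.begin() + ((arma::uword)c + (arma::uword)C * n) * Ho * Wo;
      for (arma::uword p = 0; p < (arma::uword)Ho * Wo; ++p) xs[is[p]] += ys[p];
    }
  return dx;
}

// Transpose convolution, fixed 2x2 kernel, stride 2: y(2h+i, 2w+j, co) +=
// sum_ci x(h, w, ci) * w(i, j, ci, co). Implemented as four GEMMs (one per
// kernel tap) with strided scatter into the upsampled grid.
// [[Rcpp::export]]
NumericVector upconv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = dims4(x), dw = dims4(w);
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int Cout = dw[3];
  if (dw[0] != 2 || dw[1] != 2 || dw[2] != Cin) stop("upconv weight shape");
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = alloc4(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (arma::uword)n * H * W * Cin,
                (arma::uword)H * W, Cin, false, true);
    for (int j = 0; j < 2; ++j)
      for (int i = 0; i < 2; ++i) {
        arma::mat Wij(Cin, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            Wij(ci, co) = w[i + 2 * j + 4 * ci + 4 * Cin * co];
        arma::mat Y = X * Wij;  // (H*W, Cout)
        for (int co = 0; co < Cout; ++co) {
          double* ys = y.begin() + ((arma::uword)co + (arma::uword)Cout * n) * Ho * Wo;
          const double* yc = Y.colptr(co);
          for (int wq = 0; wq < W; ++wq)
            for (int h = 0; h < H; ++h)
              ys[(2 * h + i) + Ho * (2 * wq + j)] = yc[h + H * wq];
        }
      }
    for (int co = 0; co < Cout; ++co) {
      double* ys = y.begin() + ((arma::uword)co + (arma::uword)Cout * n) * Ho * Wo;
      for (arma::uword p = 0; p < (arma::uword)Ho * Wo; ++p) ys[p] += b[co];
    }
  }
  return y;
}

// [[Rcpp::export]]
List upconv_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector dx_ = dims4(x), dw_ = dims4(w), ddy = dims4(dy);
  const int H = dx_[0], W = dx_[1], Cin = dx_[2], N = dx_[3];
  const int Cout = dw_[3];
  const int Ho = ddy[0], Wo = ddy[1];
  NumericVector dx = alloc4(H, W, Cin, N);
  NumericVector dw = alloc4(2, 2, Cin, Cout);
  NumericVector db(Cout);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (arma::uword)n * H * W * Cin,
                (arma::uword)H * W, Cin, false, true);
    arma::mat dX(dx.begin() + (arma::uword)n * H * W * Cin, (arma::uword)H * W,
                 Cin, false, true);
    for (int j = 0; j < 2; ++j)
      for (int i = 0; i < 2; ++i) {
        arma::mat dYij((arma::uword)H * W, Cout);
        for (int co = 0; co < Cout; ++co) {
          const double* ys = dy.begin() +
                             ((arma::uword)co + (arma::uword)Cout * n) * Ho * Wo;
          double* dc = dYij.colptr(co);
          for (int wq = 0; wq < W; ++wq)
            for (int h = 0; h < H; ++h)
              dc[h + H * wq] = ys[(2 * h + i) + Ho * (2 * wq + j)];
        }
        arma::mat Wij(Cin, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            Wij(ci, co) = w[i + 2 * j + 4 * ci + 4 * Cin * co];
        dX += dYij * Wij.t();
        arma::mat dWij = X.t() * dYij;  // (Cin, Cout)
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            dw[i + 2 * j + 4 * ci + 4 * Cin * co] += dWij(ci, co);
      }
  }
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* ys = dy.begin() +
                         ((arma::uword)co + (arma::uword)Cout * n) * Ho * Wo;
      double s = 0.0;
      for (arma::uword p = 0; p < (arma::uword)Ho * Wo; ++p) s += ys[p];
      db[co] += s;
    }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Batch normalisation over (H, W, N) per channel; biased variance is used
// both for normalisation and the running estimate.
// [[Rcpp::export]]
List bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
            NumericVector rmean, NumericVector rvar, double momentum,
            double eps, bool training) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const arma::uword HW = (arma::uword)H * W;
  NumericVector y = alloc4(H, W, C, N);
  NumericVector xhat = alloc4(H, W, C, N);
  NumericVector invstd(C), newmean(C), newvar(C);
  for (int c = 0; c < C; ++c) {
    double mu, var;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xs = x.begin() + ((arma::uword)c + (arma::uword)C * n) * HW;
        for (arma::uword p = 0; p < HW; ++p) { s += xs[p]; s2 += xs[p] * xs[p]; }
      }
      const double M = (double)HW * N;
      mu = s / M;
      var = s2 / M - mu * mu;
      if (var < 0) var = 0;
      newmean[c] = momentum * rmean[c] + (1 - momentum) * mu;
      newvar[c] = momentum * rvar[c] + (1 - momentum) * var;
    } else {
      mu = rmean[c];
      var = rvar[c];
      newmean[c] = rmean[c];
      newvar[c] = rvar[c];
    }
    const double is = 1.0 / std::sqrt(var + eps);
    invstd[c] = is;
    const double g = gamma[c], be = beta[c];
    for (int n = 0; n < N; ++n) {
      const arma::uword off = ((arma::uword)c + (arma::uword)C * n) * HW;
      const double* xs = x.begin() + off;
      double* hs = xhat.begin() + off;
      double* ys = y.begin() + off;
      for (arma::uword p = 0; p < HW; ++p) {
        hs[p] = (xs[p] - mu) * is;
        ys[p] = g * hs[p] + be;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["rmean"] = newmean, _["rvar"] = newvar);
}

// [[Rcpp::export]]
List bn_bwd(NumericVector xhat, NumericVector invstd, NumericVector gamma,
            NumericVector dy) {
  IntegerVector d = dims4(dy);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const arma::uword HW = (arma::uword)H * W;
  const double M = (double)HW * N;
  NumericVector dx = alloc4(H, W, C, N);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sd = 0.0, sdh = 0.0;
    for (int n = 0; n < N; ++n) {
      const arma::uword off = ((arma::uword)c + (arma::uword)C * n) * HW;
      const double* hs = xhat.begin() + off;
      const double* ds = dy.begin() + off;
      for (arma::uword p = 0; p < HW; ++p) { sd += ds[p]; sdh += ds[p] * hs[p]; }
    }
    dgamma[c] = sdh;
    dbeta[c] = sd;
    const double k = gamma[c] * invstd[c];
    const double mdy = sd / M, mdyh = sdh / M;
    for (int n = 0; n < N; ++n) {
      const arma::uword off = ((arma::uword)c + (arma::uword)C * n) * HW;
      const double* hs = xhat.begin() + off;
      const double* ds = dy.begin() + off;
      double* xs = dx.begin() + off;
      for (arma::uword p = 0; p < HW; ++p)
        xs[p] = k * (ds[p] - mdy - hs[p] * mdyh);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
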