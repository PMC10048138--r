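// Low-level layer kernels.  Tensor layout throughout: column-major R arrays
// [H, W, C, N] (height fastest), weights [kh, kw, Cin/groups, Cout].
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int H, int k, int s, int p, int d) {
  return (H + 2 * p - d * (k - 1) - 1) / s + 1;
}

// Unfold one sample's channels [c0, c0+nc) into col (nc*kh*kw x Ho*Wo),
// row index i + kh*(j + kw*c), column index ho + Ho*wo.
static void im2col(const double* x, int H, int W, int c0, int nc,
                   int kh, int kw, int s, int p, int d, int Ho, int Wo,
                   arma::mat& col) {
  const size_t ldc = col.n_rows;
  for (int c = 0; c < nc; ++c) {
    const double* xc = x + (size_t)(c0 + c) * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        double* crow = col.memptr() + (i + kh * (j + kw * c));
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * s - p + j * d;
          bool wok = (wi >= 0 && wi < W);
          const double* xcol = xc + (size_t)(wok ? wi : 0) * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * s - p + i * d;
            double v = 0.0;
            if (wok && hi >= 0 && hi < H) v = xcol[hi];
            crow[(size_t)(wo * Ho + ho) * ldc] = v;
          }
        }
      }
    }
  }
}

// Transpose of im2col: scatter-add col back onto the input grid.
static void col2im_add(const arma::mat& col, double* x, int H, int W, int c0,
                       int nc, int kh, int kw, int s, int p, int d,
                       int Ho, int Wo) {
  const size_t ldc = col.n_rows;
  for (int c = 0; c < nc; ++c) {
    double* xc = x + (size_t)(c0 + c) * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const double* crow = col.memptr() + (i + kh * (j + kw * c));
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * s - p + j * d;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * s - p + i * d;
            if (hi < 0 || hi >= H) continue;
            xcol[hi] += crow[(size_t)(wo * Ho + ho) * ldc];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad, int dil, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  if (Cg * groups != C) stop("conv2d: input channels %d incompatible with weight %d x %d groups", C, Cg, groups);
  int Ho = out_size(H, kh, stride, pad, dil), Wo = out_size(W, kw, stride, pad, dil);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: non-positive output size");
  int Coutg = Cout / groups, K = Cg * kh * kw;
  size_t S = (size_t)Ho * Wo;
  NumericVector y(S * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::mat col(K, S);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    double* yn = y.begin() + S * Cout * n;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, g * Cg, Cg, kh, kw, stride, pad, dil, Ho, Wo, col);
      arma::mat Wg(Wm.colptr((size_t)g * Coutg), K, Coutg, false, true);
      arma::mat Yg(yn + S * (size_t)g * Coutg, S, Coutg, false, true);
      Yg = col.t() * Wg;
    }
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Cout; ++c) {
        double* p = y.begin() + S * (c + (size_t)Cout * n);
        double bc = b[c];
        for (size_t t = 0; t < S; ++t) p[t] += bc;
      }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, int dil, int groups,
                    bool need_gx, bool need_gb) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  int Coutg = Cout / groups, K = Cg * kh * kw;
  size_t S = (size_t)Ho * Wo;

  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  arma::mat GW(gw.begin(), K, Cout, false, true);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);

  NumericVector gx(need_gx ? x.size() : 0);
  if (need_gx) gx.attr("dim") = xd;

  arma::mat col(K, S), dcol(need_gx ? K : 1, need_gx ? S : 1);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    const double* gyn = gy.begin() + S * Cout * n;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, g * Cg, Cg, kh, kw, stride, pad, dil, Ho, Wo, col);
      arma::mat Gg(const_cast<double*>(gyn) + S * (size_t)g * Coutg, S, Coutg, false, true);
      arma::mat GWg(GW.colptr((size_t)g * Coutg), K, Coutg, false, true);
      GWg += col * Gg;
      if (need_gx) {
        arma::mat Wg(Wm.colptr((size_t)g * Coutg), K, Coutg, false, true);
        dcol = Wg * Gg.t();
        col2im_add(dcol, gx.begin() + (size_t)H * W * C * n, H, W, g * Cg, Cg,
                   kh, kw, stride, pad, dil, Ho, Wo);
      }
    }
  }

  NumericVector gb(need_gb ? Cout : 0);
  if (need_gb) {
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Cout; ++c) {
        const double* p = gy.begin() + S * (c + (size_t)Cout * n);
        double acc = 0.0;
        for (size_t t = 0; t < S; ++t) acc += p[t];
        gb[c] += acc;
      }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_size(H, k, stride, pad, 1), Wo = out_size(W, k, stride, pad, 1);
  size_t S = (size_t)Ho * Wo;
  NumericVector y(S * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  NumericVector idx(S * C * N);  // 0-based linear index into x (double: no overflow)
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yc = y.begin() + S * (c + (size_t)C * n);
      double* ic = idx.begin() + S * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -INFINITY;
          size_t besti = 0;
          for (int j = 0; j < k; ++j) {
            int wi = wo * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = ho * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              double v = xc[hi + (size_t)wi * H];
              if (v > best) { best = v; besti = hi + (size_t)wi * H; }
            }
          }
          yc[ho + (size_t)wo * Ho] = best;
          ic[ho + (size_t)wo * Ho] = (double)(besti + (size_t)H * W * (c + (size_t)C * n));
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, NumericVector idx, IntegerVector xdim) {
  size_t total = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(total);
  gx.attr("dim") = xdim;
  for (R_xlen_t t = 0; t < gy.size(); ++t) gx[(size_t)idx[t]] += gy[t];
  return gx;
}

// Half-pixel-centre bilinear interpolation (align_corners = false).
static void bilinear_axis(int Ho, int H, std::vector<int>& i0, std::vector<int>& i1,
                          std::vector<double>& w1) {
  i0.resize(Ho); i1.resize(Ho); w1.resize(Ho);
  for (int t = 0; t < Ho; ++t) {
    double src = (t + 0.5) * (double)H / Ho - 0.5;
    if (src < 0) src = 0;
    if (src > H - 1) src = H - 1;
    int lo = (int)std::floor(src);
    int hi = std::min(lo + 1, H - 1);
    i0[t] = lo; i1[t] = hi; w1[t] = src - lo;
  }
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_fwd(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  std::vector<int> h0, h1, w0, w1;
  std::vector<double> hw, ww;
  bilinear_axis(Ho, H, h0, h1, hw);
  bilinear_axis(Wo, W, w0, w1, ww);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        const double* cl = xc + (size_t)w0[wo] * H;
        const double* cr = xc + (size_t)w1[wo] * H;
        double b = ww[wo];
        for (int ho = 0; ho < Ho; ++ho) {
          double a = hw[ho];
          double top = cl[h0[ho]] * (1 - b) + cr[h0[ho]] * b;
          double bot = cl[h1[ho]] * (1 - b) + cr[h1[ho]] * b;
          yc[ho + (size_t)wo * Ho] = top * (1 - a) + bot * a;
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_bwd(NumericVector gy, int H, int W) {
  IntegerVector yd = gy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  std::vector<int> h0, h1, w0, w1;
  std::vector<double> hw, ww;
  bilinear_axis(Ho, H, h0, h1, hw);
  bilinear_axis(Wo, W, w0, w1, ww);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* yc = gy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        double b = ww[wo];
        double* cl = xc + (size_t)w0[wo] * H;
        double* cr = xc + (size_t)w1[wo] * H;
        for (int ho = 0; ho < Ho; ++ho) {
          double a = hw[ho], g = yc[ho + (size_t)wo * Ho];
          cl[h0[ho]] += g * (1 - a) * (1 - b);
          cl[h1[ho]] += g * a * (1 - b);
          cr[h0[ho]] += g * (1 - a) * b;
          cr[h1[ho]] += g * a * b;
        }
      }
    }
  return gx;
}
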