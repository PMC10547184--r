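// Low-level numerical kernels for the network: stride-1 same-padding 2-D
// convolution (im2col + GEMM), 2x2 max pooling, bilinear resize, and
// 8-connectivity component labeling. Tensor layout everywhere is the R array
// dim = c(H, W, C, N), column-major, so index(h,w,c,n) = h + H*(w + W*(c + C*n)).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void dims4(const NumericVector &x, int &H, int &W, int &C, int &N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// im2col for one sample: rows = H*W output pixels (h fastest), cols = kh*kw*Cin.
static void im2col(const double *x, int H, int W, int C,
                   int kh, int kw, int ph, int pw, arma::mat &col) {
  // col is H*W x kh*kw*C, zero-filled by caller
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int kidx = i + kh * (j + kw * c);
        double *dst = col.colptr(kidx);
        // output pixel (h,w) reads input (h + i - ph, w + j - pw)
        for (int w = 0; w < W; ++w) {
          int ws = w + j - pw;
          if (ws < 0 || ws >= W) continue;
          int h0 = std::max(0, ph - i), h1 = std::min(H, H + ph - i);
          const double *src = xc + (size_t)H * ws;
          double *d = dst + (size_t)H * w;
          for (int h = h0; h < h1; ++h) d[h] = src[h + i - ph];
        }
      }
    }
  }
}

// scatter-add transpose of im2col
static void col2im(const arma::mat &col, int H, int W, int C,
                   int kh, int kw, int ph, int pw, double *gx) {
  for (int c = 0; c < C; ++c) {
    double *xc = gx + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int kidx = i + kh * (j + kw * c);
        const double *src0 = col.colptr(kidx);
        for (int w = 0; w < W; ++w) {
          int ws = w + j - pw;
          if (ws < 0 || ws >= W) continue;
          int h0 = std::max(0, ph - i), h1 = std::min(H, H + ph - i);
          double *dstc = xc + (size_t)H * ws;
          const double *s = src0 + (size_t)H * w;
          for (int h = h0; h < h1; ++h) dstc[h + i - ph] += s[h];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv2d_forward")]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, C, N; dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weights must be (kh, kw, Cin, Cout)");
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat wm(w.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat col((size_t)H * W, (size_t)kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    col.zeros();
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, ph, pw, col);
    arma::mat yn(y.begin() + (size_t)H * W * Cout * n, (size_t)H * W, Cout, false, true);
    yn = col * wm;
    for (int c = 0; c < Cout; ++c) yn.col(c) += b[c];
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_backward")]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gy,
                         bool need_gx) {
  int H, W, C, N; dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  arma::mat wm(w.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  NumericVector gw((size_t)kh * kw * Cin * Cout);
  gw.attr("dim") = wd;
  arma::mat gwm(gw.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  NumericVector gb(Cout);
  NumericVector gx(need_gx ? (size_t)H * W * C * N : 0);
  if (need_gx) gx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat col((size_t)H * W, (size_t)kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    col.zeros();
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, ph, pw, col);
    arma::mat gyn((double *)gy.begin() + (size_t)H * W * Cout * n,
                  (size_t)H * W, Cout, false, true);
    gwm += col.t() * gyn;
    for (int c = 0; c < Cout; ++c) gb[c] += arma::accu(gyn.col(c));
    if (need_gx) {
      arma::mat gcol = gyn * wm.t();
      col2im(gcol, H, W, C, kh, kw, ph, pw, gx.begin() + (size_t)H * W * C * n);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".cpp_maxpool2_forward")]]
List cpp_maxpool2_forward(NumericVector x) {
  int H, W, C, N; dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("maxpool2: spatial dims must be even, got %d x %d", H, W);
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg(y.size());
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h, ++o) {
          size_t i00 = (size_t)2 * h + H * (size_t)(2 * w);
          size_t best = i00; double v = xc[i00];
          size_t cand[3] = {i00 + 1, i00 + (size_t)H, i00 + (size_t)H + 1};
          for (int k = 0; k < 3; ++k)
            if (xc[cand[k]] > v) { v = xc[cand[k]]; best = cand[k]; }
          y[o] = v;
          arg[o] = (int)(best + (size_t)H * W * (c + (size_t)C * n));
        }
    }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".cpp_maxpool2_backward")]]
NumericVector cpp_maxpool2_backward(NumericVector gy, IntegerVector argmax,
                                    IntegerVector in_dim) {
  size_t n = (size_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3];
  NumericVector gx(n);
  gx.attr("dim") = in_dim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[argmax[i]] += gy[i];
  return gx;
}

// Bilinear resize with half-pixel centers (align_corners = FALSE).
static inline void src_coord(int i, double scale, int n, int &i0, int &i1, double &t) {
  double s = (i + 0.5) * scale - 0.5;
  if (s < 0) s = 0;
  if (s > n - 1) s = n - 1;
  i0 = (int)std::floor(s);
  i1 = std::min(i0 + 1, n - 1);
  t = s - i0;
}

// [[Rcpp::export(name = ".cpp_resize_bilinear_forward")]]
NumericVector cpp_resize_bilinear_forward(NumericVector x, int Ho, int Wo) {
  int H, W, C, N; dims4(x, H, W, C, N);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  double sh = (double)H / Ho, sw = (double)W / Wo;
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> th(Ho), tw(Wo);
  for (int h = 0; h < Ho; ++h) src_coord(h, sh, H, h0[h], h1[h], th[h]);
  for (int w = 0; w < Wo; ++w) src_coord(w, sw, W, w0[w], w1[w], tw[w]);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w) {
        const double *cl = xc + (size_t)H * w0[w], *cr = xc + (size_t)H * w1[w];
        for (int h = 0; h < Ho; ++h, ++o) {
          double a = cl[h0[h]] * (1 - th[h]) + cl[h1[h]] * th[h];
          double b = cr[h0[h]] * (1 - th[h]) + cr[h1[h]] * th[h];
          y[o] = a * (1 - tw[w]) + b * tw[w];
        }
      }
    }
  return y;
}

// [[Rcpp::export(name = ".cpp_resize_bilinear_backward")]]
NumericVector cpp_resize_bilinear_backward(NumericVector gy, int H, int W) {
  int Ho, Wo, C, N; dims4(gy, Ho, Wo, C, N);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  double sh = (double)H / Ho, sw = (double)W / Wo;
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> th(Ho), tw(Wo);
  for (int h = 0; h < Ho; ++h) src_coord(h, sh, H, h0[h], h1[h], th[h]);
  for (int w = 0; w < Wo; ++w) src_coord(w, sw, W, w0[w], w1[w], tw[w]);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double *xc = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w) {
        double *cl = xc + (size_t)H * w0[w], *cr = xc + (size_t)H * w1[w];
        for (int h = 0; h < Ho; ++h, ++o) {
          double g = gy[o];
          cl[h0[h]] += g * (1 - th[h]) * (1 - tw[w]);
          cl[h1[h]] += g * th[h] * (1 - tw[w]);
          cr[h0[h]] += g * (1 - th[h]) * tw[w];
          cr[h1[h]] += g * th[h] * tw[w];
        }
      }
    }
  return gx;
}

// 8-connectivity connected components of a binary matrix; labels assigned in
// column-major scan order so the result is deterministic.
// [[Rcpp::export(name = ".cpp_label8")]]
IntegerMatrix cpp_label8(LogicalMatrix m) {
  int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int>> stack;
  int next = 0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (!m(h, w) || lab(h, w)) continue;
      ++next;
      stack.push_back({h, w});
      lab(h, w) = next;
      while (!stack.empty()) {
        auto [ch, cw] = stack.back();
        stack.pop_back();
        for (int dw = -1; dw <= 1; ++dw)
          for (int dh = -1; dh <= 1; ++dh) {
            int nh = ch + dh, nw = cw + dw;
            if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
            if (m(nh, nw) && !lab(nh, nw)) {
              lab(nh, nw) = next;
              stack.push_back({nh, nw});
            }
          }
      }
    }
  return lab;
}
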