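// Low-level numeric kernels for the attention network stack.
// All image/feature tensors are R arrays with dim (H, W, C), column-major.
// Convolution weights have dim (kh, kw, c_in, c_out); that memory layout is
// exactly the (kh*kw*c_in) x c_out matrix used by the im2col GEMM below.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out_dim(int n, int k, int pad, int stride) {
  return (n + 2 * pad - k) / stride + 1;
}

// Unfold x (H,W,C) into a (H2*W2) x (kh*kw*C) matrix; zero padding.
static arma::mat im2col(const double* x, int H, int W, int C,
                        int kh, int kw, int stride, int ph, int pw,
                        int H2, int W2) {
  arma::mat col(H2 * (arma::uword)W2, kh * (arma::uword)kw * C,
                arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int q = i + kh * (j + kw * c);
        for (int w2 = 0; w2 < W2; ++w2) {
          const int wi = w2 * stride - pw + j;
          if (wi < 0 || wi >= W) continue;
          for (int h2 = 0; h2 < H2; ++h2) {
            const int hi = h2 * stride - ph + i;
            if (hi < 0 || hi >= H) continue;
            col(h2 + (arma::uword)H2 * w2, q) = x[hi + H * (wi + (size_t)W * c)];
          }
        }
      }
    }
  }
  return col;
}

// Scatter-add a (H2*W2) x (kh*kw*C) gradient matrix back onto the input grid.
static void col2im(const arma::mat& dcol, double* dx, int H, int W, int C,
                   int kh, int kw, int stride, int ph, int pw,
                   int H2, int W2) {
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int q = i + kh * (j + kw * c);
        for (int w2 = 0; w2 < W2; ++w2) {
          const int wi = w2 * stride - pw + j;
          if (wi < 0 || wi >= W) continue;
          for (int h2 = 0; h2 < H2; ++h2) {
            const int hi = h2 * stride - ph + i;
            if (hi < 0 || hi >= H) continue;
            dx[hi + H * (wi + (size_t)W * c)] += dcol(h2 + (arma::uword)H2 * w2, q);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kh = wd[0], kw = wd[1], ci = wd[2], co = wd[3];
  if (ci != C) stop("conv2d: input has %d channels but weights expect %d", C, ci);
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int H2 = conv_out_dim(H, kh, ph, stride);
  const int W2 = conv_out_dim(W, kw, pw, stride);
  arma::mat col = im2col(x.begin(), H, W, C, kh, kw, stride, ph, pw, H2, W2);
  const arma::mat wm(const_cast<double*>(w.begin()),
                     (arma::uword)kh * kw * ci, co, false, true);
  arma::mat out = col * wm;
  out.each_row() += arma::rowvec(const_cast<double*>(b.begin()), co, false, true);
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(H2, W2, co);
  return res;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gout,
                int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kh = wd[0], kw = wd[1], ci = wd[2], co = wd[3];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int H2 = conv_out_dim(H, kh, ph, stride);
  const int W2 = conv_out_dim(W, kw, pw, stride);
  arma::mat col = im2col(x.begin(), H, W, C, kh, kw, stride, ph, pw, H2, W2);
  const arma::mat wm(const_cast<double*>(w.begin()),
                     (arma::uword)kh * kw * ci, co, false, true);
  const arma::mat gm(const_cast<double*>(gout.begin()),
                     (arma::uword)H2 * W2, co, false, true);
  arma::mat dwm = col.t() * gm;
  arma::rowvec dbv = arma::sum(gm, 0);
  arma::mat dcol = gm * wm.t();
  NumericVector dx(x.size());
  col2im(dcol, dx.begin(), H, W, C, kh, kw, stride, ph, pw, H2, W2);
  dx.attr("dim") = xd;
  NumericVector dw(dwm.begin(), dwm.end());
  dw.attr("dim") = wd;
  NumericVector db(dbv.begin(), dbv.end());
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 stride-2 max pooling; returns pooled values and 1-based argmax indices.
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int H2 = H / 2, W2 = W / 2;
  NumericVector out((size_t)H2 * W2 * C);
  IntegerVector idx((size_t)H2 * W2 * C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c)
    for (int w2 = 0; w2 < W2; ++w2)
      for (int h2 = 0; h2 < H2; ++h2) {
        double best = -INFINITY; size_t barg = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const size_t k = (2 * h2 + di) + (size_t)H * ((2 * w2 + dj) + (size_t)W * c);
            if (px[k] > best) { best = px[k]; barg = k; }
          }
        const size_t o = h2 + (size_t)H2 * (w2 + (size_t)W2 * c);
        out[o] = best;
        idx[o] = (int)(barg + 1);
      }
  out.attr("dim") = IntegerVector::create(H2, W2, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector gout, IntegerVector idx,
                           IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2]);
  for (R_xlen_t i = 0; i < gout.size(); ++i) dx[idx[i] - 1] += gout[i];
  dx.attr("dim") = xdim;
  return dx;
}

struct BilinW { int i0, i1; double w; };

static std::vector<BilinW> bilin_axis(int n_in, int n_out) {
  // half-pixel-center convention: src = (i + 0.5) * n_in / n_out - 0.5
  std::vector<BilinW> v((size_t)n_out);
  for (int i = 0; i < n_out; ++i) {
    double s = (i + 0.5) * (double)n_in / n_out - 0.5;
    if (s < 0) s = 0;
    if (s > n_in - 1) s = n_in - 1;
    int i0 = (int)std::floor(s);
    int i1 = std::min(i0 + 1, n_in - 1);
    v[i] = {i0, i1, s - i0};
  }
  return v;
}

// [[Rcpp::export(name = ".bilinear_fwd")]]
NumericVector bilinear_fwd(NumericVector x, int th, int tw) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  std::vector<BilinW> rh = bilin_axis(H, th), rw = bilin_axis(W, tw);
  NumericVector out((size_t)th * tw * C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < tw; ++j) {
      const BilinW& bw = rw[j];
      for (int i = 0; i < th; ++i) {
        const BilinW& bh = rh[i];
        const size_t base = (size_t)H * W * c;
        const double v00 = px[bh.i0 + (size_t)H * bw.i0 + base];
        const double v10 = px[bh.i1 + (size_t)H * bw.i0 + base];
        const double v01 = px[bh.i0 + (size_t)H * bw.i1 + base];
        const double v11 = px[bh.i1 + (size_t)H * bw.i1 + base];
        out[i + (size_t)th * (j + (size_t)tw * c)] =
          (1 - bh.w) * (1 - bw.w) * v00 + bh.w * (1 - bw.w) * v10 +
          (1 - bh.w) * bw.w * v01 + bh.w * bw.w * v11;
      }
    }
  out.attr("dim") = IntegerVector::create(th, tw, C);
  return out;
}

// [[Rcpp::export(name = ".bilinear_bwd")]]
NumericVector bilinear_bwd(NumericVector gout, IntegerVector xdim) {
  IntegerVector gd = gout.attr("dim");
  const int th = gd[0], tw = gd[1], C = gd[2];
  const int H = xdim[0], W = xdim[1];
  std::vector<BilinW> rh = bilin_axis(H, th), rw = bilin_axis(W, tw);
  NumericVector dx((size_t)H * W * xdim[2]);
  const double* pg = gout.begin();
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < tw; ++j) {
      const BilinW& bw = rw[j];
      for (int i = 0; i < th; ++i) {
        const BilinW& bh = rh[i];
        const double g = pg[i + (size_t)th * (j + (size_t)tw * c)];
        const size_t base = (size_t)H * W * c;
        dx[bh.i0 + (size_t)H * bw.i0 + base] += (1 - bh.w) * (1 - bw.w) * g;
        dx[bh.i1 + (size_t)H * bw.i0 + base] += bh.w * (1 - bw.w) * g;
        dx[bh.i0 + (size_t)H * bw.i1 + base] += (1 - bh.w) * bw.w * g;
        dx[bh.i1 + (size_t)H * bw.i1 + base] += bh.w * bw.w * g;
      }
    }
  dx.attr("dim") = xdim;
  return dx;
}
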