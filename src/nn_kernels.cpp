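// Low-level kernels for the CPU detector: im2col/col2im convolution
// plumbing, depthwise 3x3 convolution, and stride-1 same-shape max pooling
// (the building block of the padded spatial-pyramid-pooling unit).
//
// Feature maps are R arrays [H, W, C], column-major: index h + H*w + H*W*c.
// im2col rows index output pixels (r = i + Hout*j), columns index
// (kh, kw, c) as p + KH*q + KH*KW*c, so a convolution is cols %*% Wmat.

#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericVector& x, int H, int W, int C,
                         int KH, int KW, int sh, int sw,
                         int pt, int pl, int Hout, int Wout) {
  NumericMatrix out(Hout * Wout, KH * KW * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (R_xlen_t)H * W * c;
    for (int q = 0; q < KW; ++q) {
      for (int p = 0; p < KH; ++p) {
        double* col = out.begin() +
          (R_xlen_t)(p + KH * q + KH * KW * c) * (Hout * Wout);
        for (int j = 0; j < Wout; ++j) {
          int wsrc = j * sw - pl + q;
          bool w_ok = (wsrc >= 0 && wsrc < W);
          for (int i = 0; i < Hout; ++i) {
            int hsrc = i * sh - pt + p;
            double v = 0.0;
            if (w_ok && hsrc >= 0 && hsrc < H)
              v = xc[hsrc + (R_xlen_t)H * wsrc];
            col[i + (R_xlen_t)Hout * j] = v;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(const NumericMatrix& cols, int H, int W, int C,
                         int KH, int KW, int sh, int sw,
                         int pt, int pl, int Hout, int Wout) {
  NumericVector dx((R_xlen_t)H * W * C);
  for (int c = 0; c < C; ++c) {
    double* xc = dx.begin() + (R_xlen_t)H * W * c;
    for (int q = 0; q < KW; ++q) {
      for (int p = 0; p < KH; ++p) {
        const double* col = cols.begin() +
          (R_xlen_t)(p + KH * q + KH * KW * c) * (Hout * Wout);
        for (int j = 0; j < Wout; ++j) {
          int wsrc = j * sw - pl + q;
          if (wsrc < 0 || wsrc >= W) continue;
          for (int i = 0; i < Hout; ++i) {
            int hsrc = i * sh - pt + p;
            if (hsrc < 0 || hsrc >= H) continue;
            xc[hsrc + (R_xlen_t)H * wsrc] += col[i + (R_xlen_t)Hout * j];
          }
        }
      }
    }
  }
  return dx;
}

// Depthwise convolution: one KH x KW filter per channel.
// w indexed p + KH*q + KH*KW*c, bias length C.
// [[Rcpp::export]]
NumericVector dwconv_fwd_cpp(const NumericVector& x, int H, int W, int C,
                             const NumericVector& w, const NumericVector& bias,
                             int KH, int KW, int sh, int sw, int pt, int pl,
                             int Hout, int Wout) {
  NumericVector y((R_xlen_t)Hout * Wout * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (R_xlen_t)H * W * c;
    const double* wc = w.begin() + (R_xlen_t)KH * KW * c;
    double* yc = y.begin() + (R_xlen_t)Hout * Wout * c;
    for (int j = 0; j < Wout; ++j) {
      for (int i = 0; i < Hout; ++i) {
        double acc = bias[c];
        for (int q = 0; q < KW; ++q) {
          int wsrc = j * sw - pl + q;
          if (wsrc < 0 || wsrc >= W) continue;
          for (int p = 0; p < KH; ++p) {
            int hsrc = i * sh - pt + p;
            if (hsrc < 0 || hsrc >= H) continue;
            acc += xc[hsrc + (R_xlen_t)H * wsrc] * wc[p + KH * q];
          }
        }
        yc[i + (R_xlen_t)Hout * j] = acc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List dwconv_bwd_cpp(const NumericVector& x, const NumericVector& dy,
                    int H, int W, int C, const NumericVector& w,
                    int KH, int KW, int sh, int sw, int pt, int pl,
                    int Hout, int Wout) {
  NumericVector dx((R_xlen_t)H * W * C);
  NumericVector dw((R_xlen_t)KH * KW * C);
  NumericVector db((R_xlen_t)C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (R_xlen_t)H * W * c;
    const double* wc = w.begin() + (R_xlen_t)KH * KW * c;
    const double* dyc = dy.begin() + (R_xlen_t)Hout * Wout * c;
    double* dxc = dx.begin() + (R_xlen_t)H * W * c;
    double* dwc = dw.begin() + (R_xlen_t)KH * KW * c;
    for (int j = 0; j < Wout; ++j) {
      for (int i = 0; i < Hout; ++i) {
        double g = dyc[i + (R_xlen_t)Hout * j];
        if (g == 0.0) continue;
        db[c] += g;
        for (int q = 0; q < KW; ++q) {
          int wsrc = j * sw - pl + q;
          if (wsrc < 0 || wsrc >= W) continue;
          for (int p = 0; p < KH; ++p) {
            int hsrc = i * sh - pt + p;
            if (hsrc < 0 || hsrc >= H) continue;
            dxc[hsrc + (R_xlen_t)H * wsrc] += g * wc[p + KH * q];
            dwc[p + KH * q] += g * xc[hsrc + (R_xlen_t)H * wsrc];
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Stride-1 same-shape max pool with kernel k; padding floor((k-1)/2) on
// top/left and the remainder on bottom/right. Returns the pooled map and
// 1-based argmax indices into x for the backward scatter.
// [[Rcpp::export]]
List maxpool_s1_cpp(const NumericVector& x, int H, int W, int C, int k) {
  int pt = (k - 1) / 2;
  int pl = pt;
  NumericVector y((R_xlen_t)H * W * C);
  IntegerVector arg((R_xlen_t)H * W * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (R_xlen_t)H * W * c;
    double* yc = y.begin() + (R_xlen_t)H * W * c;
    int* ac = arg.begin() + (R_xlen_t)H * W * c;
    for (int j = 0; j < W; ++j) {
      int w0 = j - pl, w1 = w0 + k;
      if (w0 < 0) w0 = 0;
      if (w1 > W) w1 = W;
      for (int i = 0; i < H; ++i) {
        int h0 = i - pt, h1 = h0 + k;
        if (h0 < 0) h0 = 0;
        if (h1 > H) h1 = H;
        double best = -DBL_MAX;
        int besti = -1;
        for (int ww = w0; ww < w1; ++ww) {
          for (int hh = h0; hh < h1; ++hh) {
            double v = xc[hh + (R_xlen_t)H * ww];
            if (v > best) { best = v; besti = hh + H * ww; }
          }
        }
        yc[i + (R_xlen_t)H * j] = best;
        ac[i + (R_xlen_t)H * j] = besti + 1 + H * W * c;
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_s1_bwd_cpp(const NumericVector& dy,
                                 const IntegerVector& argmax, R_xlen_t n_in) {
  NumericVector dx(n_in);
  for (R_xlen_t t = 0; t < dy.size(); ++t)
    dx[argmax[t] - 1] += dy[t];
  return dx;
}
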