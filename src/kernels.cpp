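#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Layouts:
//  1D batches: numeric array dim (C, L, B)    -- channel fastest
//  2D batches: numeric array dim (H, W, C, B) -- height fastest
// im2col row order matches matrix(W, Cout, C*k) weight flattening:
//  1D row j = c + kk*C ; 2D row j = c + ki*C + kj*C*kh (0-based).

static inline int out_len(int L, int k, int stride, int pad, bool ceil_mode) {
  int num = L + 2 * pad - k;
  if (num < 0) return (ceil_mode && L > 0) ? 1 : 0;
  int o = num / stride + 1;
  if (ceil_mode && num % stride != 0) o += 1;
  return o;
}

// [[Rcpp::export]]
NumericMatrix im2col1d(NumericVector x, int k, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  int C = d[0], L = d[1], B = d[2];
  int Lout = out_len(L, k, stride, pad, false);
  NumericMatrix cols(C * k, Lout * B);
  const double *px = x.begin();
  double *pc = cols.begin();
  for (int b = 0; b < B; ++b) {
    const double *xb = px + (size_t)b * C * L;
    for (int l = 0; l < Lout; ++l) {
      double *col = pc + ((size_t)b * Lout + l) * (C * k);
      int start = l * stride - pad;
      for (int kk = 0; kk < k; ++kk) {
        int t = start + kk;
        if (t >= 0 && t < L) {
          const double *src = xb + (size_t)t * C;
          for (int c = 0; c < C; ++c) col[kk * C + c] = src[c];
        } else {
          for (int c = 0; c < C; ++c) col[kk * C + c] = 0.0;
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im1d(NumericMatrix cols, IntegerVector xdim, int k, int stride,
                       int pad) {
  int C = xdim[0], L = xdim[1], B = xdim[2];
  int Lout = out_len(L, k, stride, pad, false);
  NumericVector x(C * L * B);
  x.attr("dim") = xdim;
  double *px = x.begin();
  const double *pc = cols.begin();
  for (int b = 0; b < B; ++b) {
    double *xb = px + (size_t)b * C * L;
    for (int l = 0; l < Lout; ++l) {
      const double *col = pc + ((size_t)b * Lout + l) * (C * k);
      int start = l * stride - pad;
      for (int kk = 0; kk < k; ++kk) {
        int t = start + kk;
        if (t >= 0 && t < L) {
          double *dst = xb + (size_t)t * C;
          for (int c = 0; c < C; ++c) dst[c] += col[kk * C + c];
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
List maxpool1d(NumericVector x, int k, int stride, bool ceil_mode) {
  IntegerVector d = x.attr("dim");
  int C = d[0], L = d[1], B = d[2];
  int Lout = out_len(L, k, stride, 0, ceil_mode);
  NumericVector y(C * Lout * B);
  IntegerVector idx(C * Lout * B); // 1-based flat index into x
  y.attr("dim") = IntegerVector::create(C, Lout, B);
  const double *px = x.begin();
  for (int b = 0; b < B; ++b) {
    for (int l = 0; l < Lout; ++l) {
      int start = l * stride;
      int end = std::min(start + k, L);
      for (int c = 0; c < C; ++c) {
        double best = -DBL_MAX;
        int besti = -1;
        for (int t = start; t < end; ++t) {
          double v = px[(size_t)b * C * L + (size_t)t * C + c];
          if (v > best) { best = v; besti = t; }
        }
        size_t o = (size_t)b * C * Lout + (size_t)l * C + c;
        y[o] = best;
        idx[o] = (int)((size_t)b * C * L + (size_t)besti * C + c) + 1;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector pool_backward(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * (xdim.size() == 3 ? xdim[2] : xdim[2] * xdim[3]));
  if (xdim.size() == 3)
    dx.attr("dim") = IntegerVector::create(xdim[0], xdim[1], xdim[2]);
  else
    dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}

// [[Rcpp::export]]
List globalmaxpool1d(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int C = d[0], L = d[1], B = d[2];
  NumericMatrix y(C, B);
  IntegerMatrix idx(C, B);
  const double *px = x.begin();
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      double best = -DBL_MAX; int besti = 0;
      for (int t = 0; t < L; ++t) {
        double v = px[(size_t)b * C * L + (size_t)t * C + c];
        if (v > best) { best = v; besti = t; }
      }
      y(c, b) = best;
      idx(c, b) = (int)((size_t)b * C * L + (size_t)besti * C + c) + 1;
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// ---------------- 2D ----------------

// [[Rcpp::export]]
NumericMatrix im2col2d(NumericVector x, int kh, int kw, int sh, int sw, int ph,
                       int pw) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], B = d[3];
  int Hout = out_len(H, kh, sh, ph, false);
  int Wout = out_len(W, kw, sw, pw, false);
  NumericMatrix cols(C * kh * kw, Hout * Wout * B);
  const double *px = x.begin();
  double *pc = cols.begin();
  size_t plane = (size_t)H * W;
  for (int b = 0; b < B; ++b) {
    const double *xb = px + (size_t)b * plane * C;
    for (int wo = 0; wo < Wout; ++wo) {
      for (int ho = 0; ho < Hout; ++ho) {
        size_t colix = (size_t)b * Hout * Wout + (size_t)wo * Hout + ho;
        double *col = pc + colix * (C * kh * kw);
        int hstart = ho * sh - ph, wstart = wo * sw - pw;
        for (int kj = 0; kj < kw; ++kj) {
          int ww = wstart + kj;
          for (int ki = 0; ki < kh; ++ki) {
            int hh = hstart + ki;
            size_t r = (size_t)kj * C * kh + (size_t)ki * C;
            if (hh >= 0 && hh < H && ww >= 0 && ww < W) {
              for (int c = 0; c < C; ++c)
                col[r + c] = xb[(size_t)c * plane + (size_t)ww * H + hh];
            } else {
              for (int c = 0; c < C; ++c) col[r + c] = 0.0;
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im2d(NumericMatrix cols, IntegerVector xdim, int kh, int kw,
                       int sh, int sw, int ph, int pw) {
  int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  int Hout = out_len(H, kh, sh, ph, false);
  int Wout = out_len(W, kw, sw, pw, false);
  NumericVector x((size_t)H * W * C * B);
  x.attr("dim") = xdim;
  double *px = x.begin();
  const double *pc = cols.begin();
  size_t plane = (size_t)H * W;
  for (int b = 0; b < B; ++b) {
    double *xb = px + (size_t)b * plane * C;
    for (int wo = 0; wo < Wout; ++wo) {
      for (int ho = 0; ho < Hout; ++ho) {
        size_t colix = (size_t)b * Hout * Wout + (size_t)wo * Hout + ho;
        const double *col = pc + colix * (C * kh * kw);
        int hstart = ho * sh - ph, wstart = wo * sw - pw;
        for (int kj = 0; kj < kw; ++kj) {
          int ww = wstart + kj;
          for (int ki = 0; ki < kh; ++ki) {
            int hh = hstart + ki;
            size_t r = (size_t)kj * C * kh + (size_t)ki * C;
            if (hh >= 0 && hh < H && ww >= 0 && ww < W) {
              for (int c = 0; c < C; ++c)
                xb[(size_t)c * plane + (size_t)ww * H + hh] += col[r + c];
            }
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
List maxpool2d(NumericVector x, int k, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], B = d[3];
  int Hout = out_len(H, k, stride, pad, false);
  int Wout = out_len(W, k, stride, pad, false);
  NumericVector y((size_t)Hout * Wout * C * B);
  IntegerVector idx((size_t)Hout * Wout * C * B);
  y.attr("dim") = IntegerVector::create(Hout, Wout, C, B);
  const double *px = x.begin();
  size_t plane = (size_t)H * W, oplane = (size_t)Hout * Wout;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double *xc = px + (size_t)b * plane * C + (size_t)c * plane;
      for (int wo = 0; wo < Wout; ++wo) {
        for (int ho = 0; ho < Hout; ++ho) {
          int hstart = ho * stride - pad, wstart = wo * stride - pad;
          double best = -DBL_MAX; size_t besti = 0;
          for (int kj = 0; kj < k; ++kj) {
            int ww = wstart + kj;
            if (ww < 0 || ww >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hh = hstart + ki;
              if (hh < 0 || hh >= H) continue;
              double v = xc[(size_t)ww * H + hh];
              if (v > best) { best = v; besti = (size_t)ww * H + hh; }
            }
          }
          size_t o = (size_t)b * oplane * C + (size_t)c * oplane +
                     (size_t)wo * Hout + ho;
          y[o] = best;
          idx[o] = (int)((size_t)b * plane * C + (size_t)c * plane + besti) + 1;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector avgpool2d(NumericVector x, int k, int stride) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], B = d[3];
  int Hout = out_len(H, k, stride, 0, false);
  int Wout = out_len(W, k, stride, 0, false);
  NumericVector y((size_t)Hout * Wout * C * B);
  y.attr("dim") = IntegerVector::create(Hout, Wout, C, B);
  const double *px = x.begin();
  size_t plane = (size_t)H * W, oplane = (size_t)Hout * Wout;
  double inv = 1.0 / (k * k);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double *xc = px + (size_t)b * plane * C + (size_t)c * plane;
      for (int wo = 0; wo < Wout; ++wo)
        for (int ho = 0; ho < Hout; ++ho) {
          double s = 0;
          for (int kj = 0; kj < k; ++kj)
            for (int ki = 0; ki < k; ++ki)
              s += xc[(size_t)(wo * stride + kj) * H + ho * stride + ki];
          y[(size_t)b * oplane * C + (size_t)c * oplane + (size_t)wo * Hout + ho] =
              s * inv;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool2d_backward(NumericVector dy, IntegerVector xdim, int k,
                                 int stride) {
  int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  int Hout = out_len(H, k, stride, 0, false);
  int Wout = out_len(W, k, stride, 0, false);
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = xdim;
  const double *pdy = dy.begin();
  double *pdx = dx.begin();
  size_t plane = (size_t)H * W, oplane = (size_t)Hout * Wout;
  double inv = 1.0 / (k * k);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      double *xc = pdx + (size_t)b * plane * C + (size_t)c * plane;
      for (int wo = 0; wo < Wout; ++wo)
        for (int ho = 0; ho < Hout; ++ho) {
          double g = pdy[(size_t)b * oplane * C + (size_t)c * oplane +
                         (size_t)wo * Hout + ho] * inv;
          for (int kj = 0; kj < k; ++kj)
            for (int ki = 0; ki < k; ++ki)
              xc[(size_t)(wo * stride + kj) * H + ho * stride + ki] += g;
        }
    }
  return dx;
}
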