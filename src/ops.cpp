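#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Column expansion of a batch of channel-first images for convolution.
// x is an array (C, H, W, B) in R's column-major layout. The output matrix
// has k*k*C rows (channel fastest, then kernel row, then kernel column) and
// one column per (output position, batch image) pair, positions
// column-major over (outH, outW), batch-major outermost -- so a conv
// output computed as crossprod(W, cols) reshapes to (M, outH, outW, B)
// without any permutation.
// [[Rcpp::export]]
NumericMatrix im2col_cf(NumericVector x, int C, int H, int W, int B,
                        int k, int stride) {
  int outH = (H - k) / stride + 1;
  int outW = (W - k) / stride + 1;
  int P = outH * outW;
  int kkC = k * k * C;
  NumericMatrix out(kkC, P * B);
  const double *xp = x.begin();
  double *op = out.begin();
  for (int b = 0; b < B; ++b) {
    for (int ow = 0; ow < outW; ++ow) {
      for (int oh = 0; oh < outH; ++oh) {
        double *col = op + (size_t)kkC * ((size_t)b * P + ow * outH + oh);
        for (int kw = 0; kw < k; ++kw) {
          int w = ow * stride + kw;
          for (int kh = 0; kh < k; ++kh) {
            int h = oh * stride + kh;
            const double *src = xp + (size_t)C * (h + (size_t)H * (w + (size_t)W * b));
            double *dst = col + (size_t)C * (kh + k * kw);
            std::copy(src, src + C, dst);
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cf: scatter-add column gradients back onto the image.
// [[Rcpp::export]]
NumericVector col2im_cf(NumericMatrix cols, int C, int H, int W, int B,
                        int k, int stride) {
  int outH = (H - k) / stride + 1;
  int outW = (W - k) / stride + 1;
  int P = outH * outW;
  int kkC = k * k * C;
  NumericVector dx((size_t)C * H * W * B);
  double *xp = dx.begin();
  const double *op = cols.begin();
  for (int b = 0; b < B; ++b) {
    for (int ow = 0; ow < outW; ++ow) {
      for (int oh = 0; oh < outH; ++oh) {
        const double *col = op + (size_t)kkC * ((size_t)b * P + ow * outH + oh);
        for (int kw = 0; kw < k; ++kw) {
          int w = ow * stride + kw;
          for (int kh = 0; kh < k; ++kh) {
            int h = oh * stride + kh;
            double *dst = xp + (size_t)C * (h + (size_t)H * (w + (size_t)W * b));
            const double *src = col + (size_t)C * (kh + k * kw);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  return dx;
}

// Average pooling over (p x p) spatial windows with the given stride, per
// channel, on channel-first (C, H, W, B) arrays.
// [[Rcpp::export]]
NumericVector avgpool_cf_fwd(NumericVector x, int C, int H, int W, int B,
                             int p, int stride) {
  int outH = (H - p) / stride + 1;
  int outW = (W - p) / stride + 1;
  NumericVector y((size_t)C * outH * outW * B);
  const double inv = 1.0 / (p * p);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int b = 0; b < B; ++b) {
    for (int ow = 0; ow < outW; ++ow) {
      for (int oh = 0; oh < outH; ++oh) {
        double *out = yp + (size_t)C * (oh + (size_t)outH * (ow + (size_t)outW * b));
        for (int c = 0; c < C; ++c) out[c] = 0.0;
        for (int kw = 0; kw < p; ++kw) {
          int w = ow * stride + kw;
          for (int kh = 0; kh < p; ++kh) {
            int h = oh * stride + kh;
            const double *src = xp + (size_t)C * (h + (size_t)H * (w + (size_t)W * b));
            for (int c = 0; c < C; ++c) out[c] += src[c];
          }
        }
        for (int c = 0; c < C; ++c) out[c] *= inv;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool_cf_bwd(NumericVector dy, int C, int H, int W, int B,
                             int p, int stride) {
  int outH = (H - p) / stride + 1;
  int outW = (W - p) / stride + 1;
  NumericVector dx((size_t)C * H * W * B);
  const double inv = 1.0 / (p * p);
  const double *gp = dy.begin();
  double *xp = dx.begin();
  for (int b = 0; b < B; ++b) {
    for (int ow = 0; ow < outW; ++ow) {
      for (int oh = 0; oh < outH; ++oh) {
        const double *g = gp + (size_t)C * (oh + (size_t)outH * (ow + (size_t)outW * b));
        for (int kw = 0; kw < p; ++kw) {
          int w = ow * stride + kw;
          for (int kh = 0; kh < p; ++kh) {
            int h = oh * stride + kh;
            double *dst = xp + (size_t)C * (h + (size_t)H * (w + (size_t)W * b));
            for (int c = 0; c < C; ++c) dst[c] += g[c] * inv;
          }
        }
      }
    }
  }
  return dx;
}

// Dynamic-time-warping distance with absolute-difference local cost and the
// standard (i-1,j), (i,j-1), (i-1,j-1) step pattern; no alignment band.
// [[Rcpp::export]]
double dtw_dist(NumericVector a, NumericVector b) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return NA_REAL;
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = R_PosInf;
    double ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      double cost = std::fabs(ai - b[j - 1]);
      double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = cost + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// In-place fused bias add + leaky rectification on a conv response matrix
// z of shape (M x P*B) freshly produced by crossprod (the caller owns the
// buffer). Returns the same object.
// [[Rcpp::export]]
NumericMatrix bias_leaky_inplace(NumericMatrix z, NumericVector b,
                                 double slope) {
  int M = z.nrow();
  R_xlen_t n = (R_xlen_t)z.nrow() * z.ncol();
  double *p = z.begin();
  const double *bp = b.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = p[i] + bp[i % M];
    p[i] = v > 0 ? v : slope * v;
  }
  return z;
}

// In-place multiply of a gradient buffer by the leaky-rectifier derivative
// evaluated from the activation sign (a > 0 -> 1, else slope). dz must be a
// freshly allocated buffer owned by the caller.
// [[Rcpp::export]]
NumericVector leaky_grad_mul_inplace(NumericVector dz, NumericVector a,
                                     double slope) {
  R_xlen_t n = dz.size();
  double *p = dz.begin();
  const double *ap = a.begin();
  for (R_xlen_t i = 0; i < n; ++i)
    if (ap[i] <= 0) p[i] *= slope;
  return dz;
}
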