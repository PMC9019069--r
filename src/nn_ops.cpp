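// Low-level tensor kernels for the CNN engine.
// Tensor layout throughout: column-major R arrays dim (H, W, C, N).
// Weight layout: (kh, kw, Cin/groups, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// Gather one sample's padded patches into col (Ho*Wo rows, kh*kw*cin cols).
// Column order: kh fastest, then kw, then cin (matches R weight flattening).
static void im2col(const double* x, int H, int W, int cin,
                   int kh, int kw, int s, int p, arma::mat& col) {
  const int Ho = out_size(H, kh, s, p), Wo = out_size(W, kw, s, p);
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        double* dst = col.colptr((size_t)c * kh * kw + (size_t)j * kh + i);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * s - p + j;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) dst[(size_t)wo * Ho + ho] = 0.0;
          } else {
            const double* xcol = xc + (size_t)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * s - p + i;
              dst[(size_t)wo * Ho + ho] =
                (hi < 0 || hi >= H) ? 0.0 : xcol[hi];
            }
          }
        }
      }
    }
  }
}

// Scatter-add col gradients back to the input gradient (reverse of im2col).
static void col2im(const arma::mat& col, int H, int W, int cin,
                   int kh, int kw, int s, int p, double* gx) {
  const int Ho = out_size(H, kh, s, p), Wo = out_size(W, kw, s, p);
  for (int c = 0; c < cin; ++c) {
    double* gc = gx + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const double* src = col.colptr((size_t)c * kh * kw + (size_t)j * kh + i);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * s - p + j;
          if (wi < 0 || wi >= W) continue;
          double* gcol = gc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * s - p + i;
            if (hi >= 0 && hi < H) gcol[hi] += src[(size_t)wo * Ho + ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             int stride, int pad, int groups) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], cing = wdim[2], cout = wdim[3];
  const int cin_g = C / groups, cout_g = cout / groups;
  if (cing != cin_g) stop("weight/input channel mismatch");
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("convolution output size is non-positive");
  NumericVector y((size_t)Ho * Wo * cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, cout, N);
  arma::mat col((size_t)Ho * Wo, (size_t)kh * kw * cin_g);
  const size_t wg = (size_t)kh * kw * cin_g * cout_g;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    double* yn = y.begin() + (size_t)n * Ho * Wo * cout;
    for (int g = 0; g < groups; ++g) {
      im2col(xn + (size_t)g * cin_g * H * W, H, W, cin_g, kh, kw, stride, pad, col);
      arma::mat Wm(const_cast<double*>(w.begin()) + g * wg,
                   (size_t)kh * kw * cin_g, cout_g, false, true);
      arma::mat Ym(yn + (size_t)g * cout_g * Ho * Wo,
                   (size_t)Ho * Wo, cout_g, false, true);
      Ym = col * Wm;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector wdim,
                    NumericVector gy, int stride, int pad, int groups,
                    bool need_gx) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], cin_g = wdim[2], cout = wdim[3];
  const int cout_g = cout / groups;
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  NumericVector gw((size_t)kh * kw * cin_g * cout);
  gw.attr("dim") = wdim;
  NumericVector gx;
  if (need_gx) { gx = NumericVector((size_t)H * W * C * N); gx.attr("dim") = xdim; }
  arma::mat col((size_t)Ho * Wo, (size_t)kh * kw * cin_g);
  const size_t wg = (size_t)kh * kw * cin_g * cout_g;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    const double* gyn = gy.begin() + (size_t)n * Ho * Wo * cout;
    for (int g = 0; g < groups; ++g) {
      im2col(xn + (size_t)g * cin_g * H * W, H, W, cin_g, kh, kw, stride, pad, col);
      arma::mat Gy(const_cast<double*>(gyn) + (size_t)g * cout_g * Ho * Wo,
                   (size_t)Ho * Wo, cout_g, false, true);
      arma::mat Gw(gw.begin() + g * wg, (size_t)kh * kw * cin_g, cout_g, false, true);
      Gw += col.t() * Gy;
      if (need_gx) {
        arma::mat gcol = Gy * arma::mat(const_cast<double*>(w.begin()) + g * wg,
                                        (size_t)kh * kw * cin_g, cout_g,
                                        false, true).t();
        col2im(gcol, H, W, cin_g, kh, kw, stride, pad,
               gx.begin() + (size_t)n * H * W * C + (size_t)g * cin_g * H * W);
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector xdim, int k, int s, int p) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((size_t)Ho * Wo * C * N); // 0-based index into (H,W) plane
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + ((size_t)n * C + c) * H * W;
      double* yp = y.begin() + ((size_t)n * C + c) * Ho * Wo;
      int* ip = idx.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300; int bidx = -1;
          for (int j = 0; j < k; ++j) {
            int wi = wo * s - p + j; if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = ho * s - p + i; if (hi < 0 || hi >= H) continue;
              double v = xp[(size_t)wi * H + hi];
              if (v > best) { best = v; bidx = wi * H + hi; }
            }
          }
          yp[(size_t)wo * Ho + ho] = best;
          ip[(size_t)wo * Ho + ho] = bidx;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector idx,
                              IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector ydim = gy.attr("dim");
  const size_t plane_o = (size_t)ydim[0] * ydim[1];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gp = gy.begin() + ((size_t)n * C + c) * plane_o;
      const int* ip = idx.begin() + ((size_t)n * C + c) * plane_o;
      double* gxp = gx.begin() + ((size_t)n * C + c) * H * W;
      for (size_t t = 0; t < plane_o; ++t)
        if (ip[t] >= 0) gxp[ip[t]] += gp[t];
    }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_fwd(NumericVector x, IntegerVector xdim,
                              int k, int s, int p) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double inv = 1.0 / (k * k); // count_include_pad
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + ((size_t)n * C + c) * H * W;
      double* yp = y.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = 0.0;
          for (int j = 0; j < k; ++j) {
            int wi = wo * s - p + j; if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = ho * s - p + i; if (hi < 0 || hi >= H) continue;
              acc += xp[(size_t)wi * H + hi];
            }
          }
          yp[(size_t)wo * Ho + ho] = acc * inv;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bwd(NumericVector gy, IntegerVector xdim,
                              int k, int s, int p) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  const double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gp = gy.begin() + ((size_t)n * C + c) * (size_t)Ho * Wo;
      double* gxp = gx.begin() + ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double g = gp[(size_t)wo * Ho + ho] * inv;
          for (int j = 0; j < k; ++j) {
            int wi = wo * s - p + j; if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = ho * s - p + i; if (hi < 0 || hi >= H) continue;
              gxp[(size_t)wi * H + hi] += g;
            }
          }
        }
    }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector y((size_t)4 * H * W * C * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xp = x.begin() + cn * H * W;
    double* yp = y.begin() + cn * 4 * H * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        double v = xp[(size_t)w * H + h];
        size_t b = (size_t)(2 * w) * 2 * H + 2 * h;
        yp[b] = v; yp[b + 1] = v;
        yp[b + 2 * H] = v; yp[b + 2 * H + 1] = v;
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector gy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* gp = gy.begin() + cn * 4 * H * W;
    double* gxp = gx.begin() + cn * H * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        size_t b = (size_t)(2 * w) * 2 * H + 2 * h;
        gxp[(size_t)w * H + h] =
          gp[b] + gp[b + 1] + gp[b + 2 * H] + gp[b + 2 * H + 1];
      }
  }
  return gx;
}
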