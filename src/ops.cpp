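// Low-level volumetric kernels: 3D convolution (vol2col + GEMM), max pooling,
// trilinear upsampling, separable Gaussian blur. Array layouts follow R's
// column-major convention; volumes are [D, H, W, C, N].
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Unfold one sample into a (k^3*Cin) x (Do*Ho*Wo) matrix. Row order matches
// the column-major flattening of a [k, k, k, Cin] weight block so the weight
// array can be used as a K x Cout matrix without copying.
static void vol2col(const double* x, int D, int H, int W, int Cin,
                    int k, int stride, int pad, arma::mat& cols) {
  const int Do = conv_out_dim(D, k, stride, pad);
  const int Ho = conv_out_dim(H, k, stride, pad);
  const int Wo = conv_out_dim(W, k, stride, pad);
  for (int wo = 0; wo < Wo; ++wo) {
    const int wi0 = wo * stride - pad;
    for (int ho = 0; ho < Ho; ++ho) {
      const int hi0 = ho * stride - pad;
      for (int dd = 0; dd < Do; ++dd) {
        const int di0 = dd * stride - pad;
        const int col = dd + Do * (ho + Ho * wo);
        double* cptr = cols.colptr(col);
        const bool interior = di0 >= 0 && di0 + k <= D && hi0 >= 0 &&
          hi0 + k <= H && wi0 >= 0 && wi0 + k <= W;
        if (interior) {
          // whole window in-bounds: contiguous copies along the fastest axis
          for (int ci = 0; ci < Cin; ++ci) {
            const double* xc = x + (size_t)ci * D * H * W;
            for (int kw = 0; kw < k; ++kw) {
              for (int kh = 0; kh < k; ++kh) {
                const double* src = xc + di0 +
                  (size_t)D * (hi0 + kh + (size_t)H * (wi0 + kw));
                double* dst = cptr + k * (kh + k * (kw + k * ci));
                std::memcpy(dst, src, k * sizeof(double));
              }
            }
          }
        } else {
          for (int ci = 0; ci < Cin; ++ci) {
            const double* xc = x + (size_t)ci * D * H * W;
            for (int kw = 0; kw < k; ++kw) {
              const int wi = wi0 + kw;
              for (int kh = 0; kh < k; ++kh) {
                const int hi = hi0 + kh;
                for (int kd = 0; kd < k; ++kd) {
                  const int di = di0 + kd;
                  const int row = kd + k * (kh + k * (kw + k * ci));
                  double v = 0.0;
                  if (di >= 0 && di < D && hi >= 0 && hi < H &&
                      wi >= 0 && wi < W)
                    v = xc[di + (size_t)D * (hi + (size_t)H * wi)];
                  cptr[row] = v;
                }
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add the columns back into a volume (adjoint of vol2col).
static void col2vol_add(const arma::mat& cols, double* gx,
                        int D, int H, int W, int Cin,
                        int k, int stride, int pad) {
  const int Do = conv_out_dim(D, k, stride, pad);
  const int Ho = conv_out_dim(H, k, stride, pad);
  const int Wo = conv_out_dim(W, k, stride, pad);
  for (int wo = 0; wo < Wo; ++wo) {
    const int wi0 = wo * stride - pad;
    for (int ho = 0; ho < Ho; ++ho) {
      const int hi0 = ho * stride - pad;
      for (int dd = 0; dd < Do; ++dd) {
        const int di0 = dd * stride - pad;
        const int col = dd + Do * (ho + Ho * wo);
        const double* cptr = cols.colptr(col);
        const bool interior = di0 >= 0 && di0 + k <= D && hi0 >= 0 &&
          hi0 + k <= H && wi0 >= 0 && wi0 + k <= W;
        if (interior) {
          for (int ci = 0; ci < Cin; ++ci) {
            double* xc = gx + (size_t)ci * D * H * W;
            for (int kw = 0; kw < k; ++kw) {
              for (int kh = 0; kh < k; ++kh) {
                double* dst = xc + di0 +
                  (size_t)D * (hi0 + kh + (size_t)H * (wi0 + kw));
                const double* src = cptr + k * (kh + k * (kw + k * ci));
                for (int kd = 0; kd < k; ++kd) dst[kd] += src[kd];
              }
            }
          }
        } else {
          for (int ci = 0; ci < Cin; ++ci) {
            double* xc = gx + (size_t)ci * D * H * W;
            for (int kw = 0; kw < k; ++kw) {
              const int wi = wi0 + kw;
              if (wi < 0 || wi >= W) continue;
              for (int kh = 0; kh < k; ++kh) {
                const int hi = hi0 + kh;
                if (hi < 0 || hi >= H) continue;
                for (int kd = 0; kd < k; ++kd) {
                  const int di = di0 + kd;
                  if (di < 0 || di >= D) continue;
                  const int row = kd + k * (kh + k * (kw + k * ci));
                  xc[di + (size_t)D * (hi + (size_t)H * wi)] += cptr[row];
                }
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, int k, int cout,
                             int stride, int pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], Cin = xdim[3], N = xdim[4];
  const int Do = conv_out_dim(D, k, stride, pad);
  const int Ho = conv_out_dim(H, k, stride, pad);
  const int Wo = conv_out_dim(W, k, stride, pad);
  if (Do < 1 || Ho < 1 || Wo < 1)
    stop("input spatial dims too small for kernel/stride");
  const int K = k * k * k * Cin;
  const size_t L = (size_t)Do * Ho * Wo;
  arma::mat Wm(w.begin(), K, cout, false);
  NumericVector out(L * cout * (size_t)N);
  arma::mat cols(K, L);
  for (int n = 0; n < N; ++n) {
    vol2col(x.begin() + (size_t)n * D * H * W * Cin, D, H, W, Cin,
            k, stride, pad, cols);
    arma::mat O(out.begin() + (size_t)n * L * cout, L, cout, false, true);
    O = cols.t() * Wm;
  }
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, cout, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xdim,
                    NumericVector w, int k, int cout,
                    int stride, int pad, NumericVector gout,
                    bool need_gx) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], Cin = xdim[3], N = xdim[4];
  const int Do = conv_out_dim(D, k, stride, pad);
  const int Ho = conv_out_dim(H, k, stride, pad);
  const int Wo = conv_out_dim(W, k, stride, pad);
  const int K = k * k * k * Cin;
  const size_t L = (size_t)Do * Ho * Wo;
  arma::mat Wm(w.begin(), K, cout, false);
  NumericVector gx(x.size());
  NumericVector gw(w.size());
  arma::mat gWm(gw.begin(), K, cout, false, true);
  arma::mat cols(K, L);
  for (int n = 0; n < N; ++n) {
    vol2col(x.begin() + (size_t)n * D * H * W * Cin, D, H, W, Cin,
            k, stride, pad, cols);
    arma::mat GO((double*)gout.begin() + (size_t)n * L * cout, L, cout,
                 false, true);
    gWm += cols * GO;
    if (need_gx) {
      arma::mat gcols = Wm * GO.t();
      col2vol_add(gcols, gx.begin() + (size_t)n * D * H * W * Cin,
                  D, H, W, Cin, k, stride, pad);
    }
  }
  gx.attr("dim") = xdim;
  gw.attr("dim") = IntegerVector::create(k, k, k, Cin, cout);
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector xdim,
                     int k, int stride, int pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  const int Do = conv_out_dim(D, k, stride, pad);
  const int Ho = conv_out_dim(H, k, stride, pad);
  const int Wo = conv_out_dim(W, k, stride, pad);
  if (Do < 1 || Ho < 1 || Wo < 1)
    stop("input spatial dims too small for pooling window");
  const size_t L = (size_t)Do * Ho * Wo;
  NumericVector out(L * C * (size_t)N);
  IntegerVector amax(L * C * (size_t)N);
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)(n * C + c) * D * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          for (int dd = 0; dd < Do; ++dd) {
            double best = R_NegInf;
            size_t besti = 0;
            for (int kw = 0; kw < k; ++kw) {
              const int wi = wo * stride - pad + kw;
              if (wi < 0 || wi >= W) continue;
              for (int kh = 0; kh < k; ++kh) {
                const int hi = ho * stride - pad + kh;
                if (hi < 0 || hi >= H) continue;
                for (int kd = 0; kd < k; ++kd) {
                  const int di = dd * stride - pad + kd;
                  if (di < 0 || di >= D) continue;
                  const size_t idx = base + di + (size_t)D * (hi + (size_t)H * wi);
                  if (x[idx] > best) { best = x[idx]; besti = idx; }
                }
              }
            }
            // output index (dd,ho,wo,c,n) in column-major order equals o
            const size_t oi = (size_t)(n * C + c) * L +
              dd + (size_t)Do * (ho + (size_t)Ho * wo);
            out[oi] = best;
            amax[oi] = (int)besti;
            ++o;
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, C, N);
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gout, IntegerVector argmax,
                              IntegerVector xdim) {
  size_t xlen = 1;
  for (int i = 0; i < xdim.size(); ++i) xlen *= (size_t)xdim[i];
  NumericVector gx(xlen);
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[argmax[i]] += gout[i];
  gx.attr("dim") = xdim;
  return gx;
}

// Corner-aligned trilinear interpolation of a single [D,H,W] volume.
// [[Rcpp::export]]
NumericVector cpp_upsample3(NumericVector x, IntegerVector idim,
                            IntegerVector odim) {
  const int D = idim[0], H = idim[1], W = idim[2];
  const int Do = odim[0], Ho = odim[1], Wo = odim[2];
  NumericVector out((size_t)Do * Ho * Wo);
  const double sd = Do > 1 ? (double)(D - 1) / (Do - 1) : 0.0;
  const double sh = Ho > 1 ? (double)(H - 1) / (Ho - 1) : 0.0;
  const double sw = Wo > 1 ? (double)(W - 1) / (Wo - 1) : 0.0;
  size_t o = 0;
  for (int wo = 0; wo < Wo; ++wo) {
    const double fw = wo * sw;
    int w0 = (int)fw; if (w0 > W - 2) w0 = W > 1 ? W - 2 : 0;
    const double tw = W > 1 ? fw - w0 : 0.0;
    for (int ho = 0; ho < Ho; ++ho) {
      const double fh = ho * sh;
      int h0 = (int)fh; if (h0 > H - 2) h0 = H > 1 ? H - 2 : 0;
      const double th = H > 1 ? fh - h0 : 0.0;
      for (int dd = 0; dd < Do; ++dd, ++o) {
        const double fd = dd * sd;
        int d0 = (int)fd; if (d0 > D - 2) d0 = D > 1 ? D - 2 : 0;
        const double td = D > 1 ? fd - d0 : 0.0;
        double acc = 0.0;
        for (int cw = 0; cw < 2; ++cw) {
          const int wi = W > 1 ? w0 + cw : 0;
          const double ww = cw ? tw : 1.0 - tw;
          if (ww == 0.0 && W > 1) continue;
          for (int ch = 0; ch < 2; ++ch) {
            const int hi = H > 1 ? h0 + ch : 0;
            const double wh = ch ? th : 1.0 - th;
            if (wh == 0.0 && H > 1) continue;
            for (int cd = 0; cd < 2; ++cd) {
              const int di = D > 1 ? d0 + cd : 0;
              const double wd = cd ? td : 1.0 - td;
              if (wd == 0.0 && D > 1) continue;
              acc += ww * wh * wd *
                x[di + (size_t)D * (hi + (size_t)H * wi)];
              if (D == 1) break;
            }
            if (H == 1) break;
          }
          if (W == 1) break;
        }
        out[o] = acc;
      }
    }
  }
  out.attr("dim") = odim;
  return out;
}

// Separable Gaussian blur of one [D,H,W] volume. Boundary handling
// renormalizes the kernel over in-bounds taps so constants are preserved.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur3(NumericVector x, IntegerVector dim3,
                              double sd, int max_radius) {
  const int D = dim3[0], H = dim3[1], W = dim3[2];
  NumericVector out = clone(x);
  if (sd <= 0) { out.attr("dim") = dim3; return out; }
  int r = (int)std::ceil(4.0 * sd);
  if (r < 1) r = 1;
  if (r > max_radius) r = max_radius;
  std::vector<double> g(2 * r + 1);
  for (int j = -r; j <= r; ++j)
    g[j + r] = std::exp(-0.5 * (double)j * j / (sd * sd));
  std::vector<double> buf((size_t)D * H * W);
  const int dims[3] = {D, H, W};
  const size_t strides[3] = {1, (size_t)D, (size_t)D * H};
  double* cur = out.begin();
  for (int axis = 0; axis < 3; ++axis) {
    const int n = dims[axis];
    const size_t st = strides[axis];
    const size_t total = (size_t)D * H * W;
    for (size_t start = 0; start < total; ++start) {
      // process each line along `axis` once: start must be the first voxel
      const size_t coord = (start / st) % n;
      if (coord != 0) continue;
      for (int i = 0; i < n; ++i) {
        double acc = 0.0, wsum = 0.0;
        const int jlo = std::max(-r, -i), jhi = std::min(r, n - 1 - i);
        for (int j = jlo; j <= jhi; ++j) {
          const double gw = g[j + r];
          acc += gw * cur[start + (size_t)(i + j) * st];
          wsum += gw;
        }
        buf[start + (size_t)i * st] = acc / wsum;
      }
    }
    std::copy(buf.begin(), buf.end(), cur);
  }
  out.attr("dim") = dim3;
  return out;
}

// Trilinear upsampling where input-grid voxel v maps to feature coordinate
// v / stride (both 0-based, offset-free for centered odd kernels), clamped at
// the far edge. Registers a downsampled feature map back onto the input grid
// of a strided convolutional network.
// [[Rcpp::export]]
NumericVector cpp_upsample3_stride(NumericVector x, IntegerVector idim,
                                   IntegerVector odim, double stride) {
  const int D = idim[0], H = idim[1], W = idim[2];
  const int Do = odim[0], Ho = odim[1], Wo = odim[2];
  NumericVector out((size_t)Do * Ho * Wo);
  size_t o = 0;
  for (int wo = 0; wo < Wo; ++wo) {
    double fw = wo / stride;
    if (fw > W - 1) fw = W - 1;
    int w0 = (int)fw; if (w0 > W - 2) w0 = W > 1 ? W - 2 : 0;
    const double tw = W > 1 ? fw - w0 : 0.0;
    for (int ho = 0; ho < Ho; ++ho) {
      double fh = ho / stride;
      if (fh > H - 1) fh = H - 1;
      int h0 = (int)fh; if (h0 > H - 2) h0 = H > 1 ? H - 2 : 0;
      const double th = H > 1 ? fh - h0 : 0.0;
      for (int dd = 0; dd < Do; ++dd, ++o) {
        double fd = dd / stride;
        if (fd > D - 1) fd = D - 1;
        int d0 = (int)fd; if (d0 > D - 2) d0 = D > 1 ? D - 2 : 0;
        const double td = D > 1 ? fd - d0 : 0.0;
        double acc = 0.0;
        for (int cw = 0; cw < 2; ++cw) {
          const int wi = W > 1 ? w0 + cw : 0;
          const double ww = cw ? tw : 1.0 - tw;
          for (int ch = 0; ch < 2; ++ch) {
            const int hi = H > 1 ? h0 + ch : 0;
            const double wh = ch ? th : 1.0 - th;
            for (int cd = 0; cd < 2; ++cd) {
              const int di = D > 1 ? d0 + cd : 0;
              const double wd = cd ? td : 1.0 - td;
              acc += ww * wh * wd *
                x[di + (size_t)D * (hi + (size_t)H * wi)];
              if (D == 1) break;
            }
            if (H == 1) break;
          }
          if (W == 1) break;
        }
        out[o] = acc;
      }
    }
  }
  out.attr("dim") = odim;
  return out;
}
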