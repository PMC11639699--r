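// Convolution kernels for the rank-4 feature-map engine.
// Layout convention matches the R side: arrays are column-major with
// dim = (batch, channel, height, width), so index(b,c,h,w) =
// b + B*(c + C*(h + H*w)).  Each kernel first repacks the batch into
// contiguous per-(b,c) spatial planes, then runs im2col + one BLAS matmul
// per channel group across the whole batch.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_extent(int in, int k, int stride, int dil, int pad) {
  return (in + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// repack (b,C,h,w) R layout into planes[b][c] contiguous (h fastest, then w)
static arma::vec repack_bchw(const double* x, int B, int C, int H, int W) {
  arma::vec xt(static_cast<size_t>(B) * C * H * W);
  double* p = xt.memptr();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      size_t off = (static_cast<size_t>(b) * C + c) * H * W;
      for (int wi = 0; wi < W; ++wi)
        for (int hi = 0; hi < H; ++hi)
          p[off + hi + static_cast<size_t>(H) * wi] =
            x[b + (size_t)B * (c + (size_t)C * (hi + (size_t)H * wi))];
    }
  return xt;
}

// inverse of repack: accumulate plane buffer back into the R layout
static void unpack_bchw(const double* planes, double* x, int B, int C, int H, int W) {
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      size_t off = (static_cast<size_t>(b) * C + c) * H * W;
      for (int wi = 0; wi < W; ++wi)
        for (int hi = 0; hi < H; ++hi)
          x[b + (size_t)B * (c + (size_t)C * (hi + (size_t)H * wi))] =
            planes[off + hi + static_cast<size_t>(H) * wi];
    }
}

// im2col over the whole batch for one channel group.
// cols: (Cipg*kh*kw) x (B*oh*ow); row r = (ci*kh + ki)*kw + kj,
// column q = b*oh*ow + (oh_i + oh*ow_i).
static void im2col_group(const double* planes, int B, int C, int H, int W,
                         int c0, int cipg, int kh, int kw,
                         int stride, int dil, int pad, int oh, int ow,
                         arma::mat& cols) {
  int nrow = cipg * kh * kw;
  double* dst = cols.memptr();
  for (int b = 0; b < B; ++b) {
    const double* pb = planes + (static_cast<size_t>(b) * C + c0) * H * W;
    for (int ow_i = 0; ow_i < ow; ++ow_i) {
      for (int oh_i = 0; oh_i < oh; ++oh_i) {
        // fill one column sequentially
        for (int ci = 0; ci < cipg; ++ci) {
          const double* pl = pb + static_cast<size_t>(ci) * H * W;
          for (int ki = 0; ki < kh; ++ki) {
            int hi = oh_i * stride - pad + ki * dil;
            bool hok = hi >= 0 && hi < H;
            for (int kj = 0; kj < kw; ++kj) {
              int wi = ow_i * stride - pad + kj * dil;
              *dst++ = (hok && wi >= 0 && wi < W)
                ? pl[hi + static_cast<size_t>(H) * wi] : 0.0;
            }
          }
        }
      }
    }
  }
  (void)nrow;
}

// adjoint of im2col_group: scatter-add cols back onto the plane buffer
static void col2im_group(double* planes, int B, int C, int H, int W,
                         int c0, int cipg, int kh, int kw,
                         int stride, int dil, int pad, int oh, int ow,
                         const arma::mat& cols) {
  const double* src = cols.memptr();
  for (int b = 0; b < B; ++b) {
    double* pb = planes + (static_cast<size_t>(b) * C + c0) * H * W;
    for (int ow_i = 0; ow_i < ow; ++ow_i) {
      for (int oh_i = 0; oh_i < oh; ++oh_i) {
        // read one column sequentially, accumulate into the planes
        for (int ci = 0; ci < cipg; ++ci) {
          double* pl = pb + static_cast<size_t>(ci) * H * W;
          for (int ki = 0; ki < kh; ++ki) {
            int hi = oh_i * stride - pad + ki * dil;
            bool hok = hi >= 0 && hi < H;
            for (int kj = 0; kj < kw; ++kj) {
              int wi = ow_i * stride - pad + kj * dil;
              double v = *src++;
              if (hok && wi >= 0 && wi < W)
                pl[hi + static_cast<size_t>(H) * wi] += v;
            }
          }
        }
      }
    }
  }
}

// Flatten weights (Co, Cipg, kh, kw) for one group into (Cipg*kh*kw) x Co_g.
static arma::mat weight_mat(const double* w, int Co, int Cipg, int kh, int kw,
                            int co0, int cog) {
  arma::mat Wm(Cipg * kh * kw, cog);
  for (int co = 0; co < cog; ++co)
    for (int ci = 0; ci < Cipg; ++ci)
      for (int ki = 0; ki < kh; ++ki)
        for (int kj = 0; kj < kw; ++kj)
          Wm((ci * kh + ki) * kw + kj, co) =
            w[(co0 + co) + (size_t)Co * (ci + (size_t)Cipg * (ki + (size_t)kh * kj))];
  return Wm;
}

// gather one output-channel group from the R layout into (cog) x (B*oh*ow)
static arma::mat gather_out_group(const double* g, int B, int Co, int oh, int ow,
                                  int co0, int cog) {
  arma::mat og(cog, static_cast<size_t>(B) * oh * ow);
  for (int b = 0; b < B; ++b)
    for (int ow_i = 0; ow_i < ow; ++ow_i)
      for (int oh_i = 0; oh_i < oh; ++oh_i) {
        size_t q = static_cast<size_t>(b) * oh * ow + static_cast<size_t>(ow_i) * oh + oh_i;
        for (int co = 0; co < cog; ++co)
          og(co, q) = g[b + (size_t)B * (co0 + co + (size_t)Co * (oh_i + (size_t)oh * ow_i))];
      }
  return og;
}

// ---------------------------------------------------------------------------
// Direct (no-im2col) paths for stride-1 convolutions: for each kernel tap,
// a contiguous saxpy over the valid output region.  Much faster than im2col
// at the small channel counts used by full-resolution stages.
// ---------------------------------------------------------------------------

static void direct_fw(const double* planes, double* outplanes,
                      const double* w, const double* bias,
                      int B, int C, int H, int W, int Co, int Cipg,
                      int kh, int kw, int dil, int pad, int oh, int ow,
                      int groups) {
  int cog = Co / groups;
  for (int b = 0; b < B; ++b)
    for (int g = 0; g < groups; ++g)
      for (int co = g * cog; co < (g + 1) * cog; ++co) {
        double* op = outplanes + (static_cast<size_t>(b) * Co + co) * oh * ow;
        double b0 = bias ? bias[co] : 0.0;
        for (size_t i = 0; i < static_cast<size_t>(oh) * ow; ++i) op[i] = b0;
        for (int ci = 0; ci < Cipg; ++ci) {
          const double* ip = planes +
            (static_cast<size_t>(b) * C + g * Cipg + ci) * H * W;
          for (int ki = 0; ki < kh; ++ki)
            for (int kj = 0; kj < kw; ++kj) {
              double wv = w[co + (size_t)Co * (ci + (size_t)Cipg * (ki + (size_t)kh * kj))];
              int dh = ki * dil - pad, dw = kj * dil - pad;
              int oh_lo = std::max(0, -dh), oh_hi = std::min(oh, H - dh);
              int ow_lo = std::max(0, -dw), ow_hi = std::min(ow, W - dw);
              for (int ow_i = ow_lo; ow_i < ow_hi; ++ow_i) {
                const double* src = ip + static_cast<size_t>(ow_i + dw) * H + dh;
                double* dst = op + static_cast<size_t>(ow_i) * oh;
                for (int oh_i = oh_lo; oh_i < oh_hi; ++oh_i)
                  dst[oh_i] += wv * src[oh_i];
              }
            }
        }
      }
}

static void direct_bw_input(double* gxplanes, const double* gyplanes,
                            const double* w,
                            int B, int Ci, int H, int W, int Co, int Cipg,
                            int kh, int kw, int dil, int pad, int oh, int ow,
                            int groups) {
  int cog = Co / groups;
  for (int b = 0; b < B; ++b)
    for (int g = 0; g < groups; ++g)
      for (int co = g * cog; co < (g + 1) * cog; ++co) {
        const double* gp = gyplanes + (static_cast<size_t>(b) * Co + co) * oh * ow;
        for (int ci = 0; ci < Cipg; ++ci) {
          double* xp = gxplanes +
            (static_cast<size_t>(b) * Ci + g * Cipg + ci) * H * W;
          for (int ki = 0; ki < kh; ++ki)
            for (int kj = 0; kj < kw; ++kj) {
              double wv = w[co + (size_t)Co * (ci + (size_t)Cipg * (ki + (size_t)kh * kj))];
              int dh = ki * dil - pad, dw = kj * dil - pad;
              int oh_lo = std::max(0, -dh), oh_hi = std::min(oh, H - dh);
              int ow_lo = std::max(0, -dw), ow_hi = std::min(ow, W - dw);
              for (int ow_i = ow_lo; ow_i < ow_hi; ++ow_i) {
                double* dst = xp + static_cast<size_t>(ow_i + dw) * H + dh;
                const double* src = gp + static_cast<size_t>(ow_i) * oh;
                for (int oh_i = oh_lo; oh_i < oh_hi; ++oh_i)
                  dst[oh_i] += wv * src[oh_i];
              }
            }
        }
      }
}

static void direct_bw_weight(const double* planes, const double* gyplanes,
                             double* gw,
                             int B, int C, int H, int W, int Co, int Cipg,
                             int kh, int kw, int dil, int pad, int oh, int ow,
                             int groups) {
  int cog = Co / groups;
  for (int g = 0; g < groups; ++g)
    for (int co = g * cog; co < (g + 1) * cog; ++co)
      for (int ci = 0; ci < Cipg; ++ci)
        for (int ki = 0; ki < kh; ++ki)
          for (int kj = 0; kj < kw; ++kj) {
            int dh = ki * dil - pad, dw = kj * dil - pad;
            int oh_lo = std::max(0, -dh), oh_hi = std::min(oh, H - dh);
            int ow_lo = std::max(0, -dw), ow_hi = std::min(ow, W - dw);
            double acc = 0.0;
            for (int b = 0; b < B; ++b) {
              const double* ip = planes +
                (static_cast<size_t>(b) * C + g * Cipg + ci) * H * W;
              const double* gp = gyplanes +
                (static_cast<size_t>(b) * Co + co) * oh * ow;
              for (int ow_i = ow_lo; ow_i < ow_hi; ++ow_i) {
                const double* src = ip + static_cast<size_t>(ow_i + dw) * H + dh;
                const double* gsrc = gp + static_cast<size_t>(ow_i) * oh;
                double a0 = 0, a1 = 0, a2 = 0, a3 = 0;
                int oh_i = oh_lo;
                for (; oh_i + 3 < oh_hi; oh_i += 4) {
                  a0 += src[oh_i] * gsrc[oh_i];
                  a1 += src[oh_i + 1] * gsrc[oh_i + 1];
                  a2 += src[oh_i + 2] * gsrc[oh_i + 2];
                  a3 += src[oh_i + 3] * gsrc[oh_i + 3];
                }
                for (; oh_i < oh_hi; ++oh_i) a0 += src[oh_i] * gsrc[oh_i];
                acc += a0 + a1 + a2 + a3;
              }
            }
            gw[co + (size_t)Co * (ci + (size_t)Cipg * (ki + (size_t)kh * kj))] = acc;
          }
}

// [[Rcpp::export(name = ".cpp_conv2d_fw")]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w,
                            Nullable<NumericVector> bias,
                            int stride, int dil, int pad, int groups) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  int B = dx[0], C = dx[1], H = dx[2], W = dx[3];
  int Co = dw[0], Cipg = dw[1], kh = dw[2], kw = dw[3];
  int oh = out_extent(H, kh, stride, dil, pad);
  int ow = out_extent(W, kw, stride, dil, pad);
  int cog = Co / groups;
  NumericVector out((size_t)B * Co * oh * ow);
  out.attr("dim") = IntegerVector::create(B, Co, oh, ow);
  double* po = out.begin();
  arma::vec planes = repack_bchw(x.begin(), B, C, H, W);
  bool has_bias = bias.isNotNull();
  NumericVector bv;
  if (has_bias) bv = NumericVector(bias);
  if (stride == 1) {
    arma::vec outp(static_cast<size_t>(B) * Co * oh * ow);
    direct_fw(planes.memptr(), outp.memptr(), w.begin(),
              has_bias ? bv.begin() : nullptr,
              B, C, H, W, Co, Cipg, kh, kw, dil, pad, oh, ow, groups);
    unpack_bchw(outp.memptr(), po, B, Co, oh, ow);
    return out;
  }
  arma::mat cols(Cipg * kh * kw, static_cast<size_t>(B) * oh * ow);
  for (int g = 0; g < groups; ++g) {
    arma::mat Wm = weight_mat(w.begin(), Co, Cipg, kh, kw, g * cog, cog);
    im2col_group(planes.memptr(), B, C, H, W, g * Cipg, Cipg, kh, kw,
                 stride, dil, pad, oh, ow, cols);
    arma::mat og = Wm.t() * cols;  // cog x (B*oh*ow)
    for (int b = 0; b < B; ++b)
      for (int ow_i = 0; ow_i < ow; ++ow_i)
        for (int oh_i = 0; oh_i < oh; ++oh_i) {
          size_t q = static_cast<size_t>(b) * oh * ow + static_cast<size_t>(ow_i) * oh + oh_i;
          for (int co = 0; co < cog; ++co) {
            double v = og(co, q);
            if (has_bias) v += bv[g * cog + co];
            po[b + (size_t)B * (g * cog + co + (size_t)Co * (oh_i + (size_t)oh * ow_i))] = v;
          }
        }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_conv2d_bw_input")]]
NumericVector cpp_conv2d_bw_input(NumericVector gy, NumericVector w,
                                  int in_h, int in_w,
                                  int stride, int dil, int pad, int groups) {
  IntegerVector dg = gy.attr("dim"), dw = w.attr("dim");
  int B = dg[0], Co = dg[1], oh = dg[2], ow = dg[3];
  int Cipg = dw[1], kh = dw[2], kw = dw[3];
  int cog = Co / groups, Ci = Cipg * groups;
  NumericVector gx((size_t)B * Ci * in_h * in_w);
  gx.attr("dim") = IntegerVector::create(B, Ci, in_h, in_w);
  arma::vec planes(static_cast<size_t>(B) * Ci * in_h * in_w, arma::fill::zeros);
  if (stride == 1) {
    arma::vec gyp = repack_bchw(gy.begin(), B, Co, oh, ow);
    direct_bw_input(planes.memptr(), gyp.memptr(), w.begin(),
                    B, Ci, in_h, in_w, Co, Cipg, kh, kw, dil, pad, oh, ow, groups);
    unpack_bchw(planes.memptr(), gx.begin(), B, Ci, in_h, in_w);
    return gx;
  }
  for (int g = 0; g < groups; ++g) {
    arma::mat Wm = weight_mat(w.begin(), Co, Cipg, kh, kw, g * cog, cog);
    arma::mat og = gather_out_group(gy.begin(), B, Co, oh, ow, g * cog, cog);
    arma::mat cols = Wm * og;  // (Cipg*kh*kw) x (B*oh*ow)
    col2im_group(planes.memptr(), B, Ci, in_h, in_w, g * Cipg, Cipg, kh, kw,
                 stride, dil, pad, oh, ow, cols);
  }
  unpack_bchw(planes.memptr(), gx.begin(), B, Ci, in_h, in_w);
  return gx;
}

// [[Rcpp::export(name = ".cpp_conv2d_bw_weight")]]
NumericVector cpp_conv2d_bw_weight(NumericVector x, NumericVector gy,
                                   int kh, int kw,
                                   int stride, int dil, int pad, int groups) {
  IntegerVector dx = x.attr("dim"), dg = gy.attr("dim");
  int B = dx[0], C = dx[1], H = dx[2], W = dx[3];
  int Co = dg[1], oh = dg[2], ow = dg[3];
  int Cipg = C / groups, cog = Co / groups;
  NumericVector gw((size_t)Co * Cipg * kh * kw);
  gw.attr("dim") = IntegerVector::create(Co, Cipg, kh, kw);
  arma::vec planes = repack_bchw(x.begin(), B, C, H, W);
  if (stride == 1) {
    arma::vec gyp = repack_bchw(gy.begin(), B, Co, oh, ow);
    direct_bw_weight(planes.memptr(), gyp.memptr(), gw.begin(),
                     B, C, H, W, Co, Cipg, kh, kw, dil, pad, oh, ow, groups);
    return gw;
  }
  arma::mat cols(Cipg * kh * kw, static_cast<size_t>(B) * oh * ow);
  for (int g = 0; g < groups; ++g) {
    im2col_group(planes.memptr(), B, C, H, W, g * Cipg, Cipg, kh, kw,
                 stride, dil, pad, oh, ow, cols);
    arma::mat og = gather_out_group(gy.begin(), B, Co, oh, ow, g * cog, cog);
    arma::mat acc = cols * og.t();  // (Cipg*kh*kw) x cog
    for (int co = 0; co < cog; ++co)
      for (int ci = 0; ci < Cipg; ++ci)
        for (int ki = 0; ki < kh; ++ki)
          for (int kj = 0; kj < kw; ++kj)
            gw[(g * cog + co) + (size_t)Co * (ci + (size_t)Cipg * (ki + (size_t)kh * kj))] =
              acc((ci * kh + ki) * kw + kj, co);
  }
  return gw;
}

// ---------------------------------------------------------------------------
// One-pass channel-wise helpers for normalization layers, operating directly
// on the (b, C, h, w) layout (no transposes).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_channel_moments")]]
NumericMatrix cpp_channel_moments(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int B = d[0], C = d[1]; size_t HW = (size_t)d[2] * d[3];
  NumericMatrix out(C, 2);
  const double* p = x.begin();
  for (size_t s = 0; s < HW; ++s)
    for (int c = 0; c < C; ++c) {
      const double* q = p + (size_t)B * (c + (size_t)C * s);
      double m = 0, v = 0;
      for (int b = 0; b < B; ++b) { m += q[b]; v += q[b] * q[b]; }
      out(c, 0) += m; out(c, 1) += v;
    }
  double n = static_cast<double>(B) * HW;
  for (int c = 0; c < C; ++c) {
    out(c, 0) /= n;
    out(c, 1) = out(c, 1) / n - out(c, 0) * out(c, 0);
  }
  return out;
}

// y = x * scale[c] + shift[c]
// [[Rcpp::export(name = ".cpp_channel_affine")]]
NumericVector cpp_channel_affine(NumericVector x, NumericVector scale,
                                 NumericVector shift) {
  IntegerVector d = x.attr("dim");
  int B = d[0], C = d[1]; size_t HW = (size_t)d[2] * d[3];
  NumericVector y(x.size());
  y.attr("dim") = d;
  const double* p = x.begin(); double* py = y.begin();
  for (size_t s = 0; s < HW; ++s)
    for (int c = 0; c < C; ++c) {
      size_t off = (size_t)B * (c + (size_t)C * s);
      double sc = scale[c], sh = shift[c];
      for (int b = 0; b < B; ++b) py[off + b] = p[off + b] * sc + sh;
    }
  return y;
}

// per-channel sum of x*y (y may be omitted -> sum of x)
// [[Rcpp::export(name = ".cpp_channel_dot")]]
NumericVector cpp_channel_dot(NumericVector x, Nullable<NumericVector> y) {
  IntegerVector d = x.attr("dim");
  int B = d[0], C = d[1]; size_t HW = (size_t)d[2] * d[3];
  NumericVector out(C);
  const double* p = x.begin();
  const double* q = y.isNotNull() ? NumericVector(y).begin() : nullptr;
  for (size_t s = 0; s < HW; ++s)
    for (int c = 0; c < C; ++c) {
      size_t off = (size_t)B * (c + (size_t)C * s);
      double acc = 0;
      if (q) for (int b = 0; b < B; ++b) acc += p[off + b] * q[off + b];
      else for (int b = 0; b < B; ++b) acc += p[off + b];
      out[c] += acc;
    }
  return out;
}
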