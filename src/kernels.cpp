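#include <Rcpp.h>
using namespace Rcpp;

// Tensor layout convention (documented once, used everywhere): R arrays with
// dim = c(H, W, C, N), column-major, zero-padding for convolutions.
// im2col column ordering is (ki, kj, c) with ki fastest, matching a weight
// array of dim c(k, k, Cin, Cout) flattened column-major to (k*k*Cin, Cout).
// im2col row ordering is (oh, ow, n) with oh fastest.

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".im2col_cpp")]]
NumericMatrix im2col_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericMatrix out((R_xlen_t)Ho * Wo * N, (R_xlen_t)k * k * C);
  const double* px = x.begin();
  double* po = out.begin();
  const R_xlen_t nrow = (R_xlen_t)Ho * Wo * N;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const R_xlen_t col = ki + (R_xlen_t)k * (kj + (R_xlen_t)k * c);
        double* pcol = po + col * nrow;
        // valid oh range: 0 <= oh*stride - pad + ki < H
        int oh_lo = 0;
        while (oh_lo * stride - pad + ki < 0) ++oh_lo;
        int oh_hi = Ho - 1;
        while (oh_hi >= 0 && oh_hi * stride - pad + ki >= H) --oh_hi;
        for (int n = 0; n < N; ++n) {
          const double* pim = px + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
          for (int ow = 0; ow < Wo; ++ow) {
            const int iw = ow * stride - pad + kj;
            double* prow = pcol + (R_xlen_t)Ho * (ow + (R_xlen_t)Wo * n);
            if (iw < 0 || iw >= W || oh_lo > oh_hi) {
              std::fill(prow, prow + Ho, 0.0);
              continue;
            }
            if (oh_lo > 0) std::fill(prow, prow + oh_lo, 0.0);
            if (oh_hi < Ho - 1) std::fill(prow + oh_hi + 1, prow + Ho, 0.0);
            const double* pin = pim + (R_xlen_t)H * iw - pad + ki;
            if (stride == 1) {
              std::copy(pin + oh_lo, pin + oh_hi + 1, prow + oh_lo);
            } else {
              for (int oh = oh_lo; oh <= oh_hi; ++oh)
                prow[oh] = pin[oh * stride];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add columns back onto the padded image grid.
// [[Rcpp::export(name = ".col2im_cpp")]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector x((R_xlen_t)H * W * C * N);
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  double* px = x.begin();
  const double* po = cols.begin();
  const R_xlen_t nrow = (R_xlen_t)Ho * Wo * N;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const R_xlen_t col = ki + (R_xlen_t)k * (kj + (R_xlen_t)k * c);
        const double* pcol = po + col * nrow;
        int oh_lo = 0;
        while (oh_lo * stride - pad + ki < 0) ++oh_lo;
        int oh_hi = Ho - 1;
        while (oh_hi >= 0 && oh_hi * stride - pad + ki >= H) --oh_hi;
        if (oh_lo > oh_hi) continue;
        for (int n = 0; n < N; ++n) {
          double* pim = px + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
          for (int ow = 0; ow < Wo; ++ow) {
            const int iw = ow * stride - pad + kj;
            if (iw < 0 || iw >= W) continue;
            const double* prow = pcol + (R_xlen_t)Ho * (ow + (R_xlen_t)Wo * n);
            double* pout = pim + (R_xlen_t)H * iw - pad + ki;
            if (stride == 1) {
              for (int oh = oh_lo; oh <= oh_hi; ++oh) pout[oh] += prow[oh];
            } else {
              for (int oh = oh_lo; oh <= oh_hi; ++oh)
                pout[oh * stride] += prow[oh];
            }
          }
        }
      }
    }
  }
  return x;
}

// Depth-wise convolution, stride 1, zero padding, kernel k x k per channel.
// w has dim c(k, k, C).
// [[Rcpp::export(name = ".dwconv_fwd_cpp")]]
NumericVector dwconv_fwd_cpp(NumericVector x, NumericVector w, int pad) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector dw = w.attr("dim");
  const int k = dw[0];
  const int Ho = out_size(H, k, 1, pad), Wo = out_size(W, k, 1, pad);
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* px = x.begin();
  const double* pw = w.begin();
  double* py = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* pim = px + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
      const double* pk = pw + (R_xlen_t)k * k * c;
      double* pout = py + ((R_xlen_t)c + (R_xlen_t)C * n) * Ho * Wo;
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          double acc = 0.0;
          for (int kj = 0; kj < k; ++kj) {
            const int iw = ow - pad + kj;
            if (iw < 0 || iw >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int ih = oh - pad + ki;
              if (ih < 0 || ih >= H) continue;
              acc += pim[ih + (R_xlen_t)H * iw] * pk[ki + k * kj];
            }
          }
          pout[oh + (R_xlen_t)Ho * ow] = acc;
        }
      }
    }
  }
  return y;
}

// Gradient of dwconv w.r.t. its input: correlation of g with the kernel
// flipped in both spatial directions (full zero-padded).
// [[Rcpp::export(name = ".dwconv_bwd_input_cpp")]]
NumericVector dwconv_bwd_input_cpp(NumericVector g, NumericVector w,
                                   int H, int W, int pad) {
  IntegerVector dg = g.attr("dim");
  const int Ho = dg[0], Wo = dg[1], C = dg[2], N = dg[3];
  IntegerVector dw = w.attr("dim");
  const int k = dw[0];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* pg = g.begin();
  const double* pw = w.begin();
  double* px = gx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* pgo = pg + ((R_xlen_t)c + (R_xlen_t)C * n) * Ho * Wo;
      const double* pk = pw + (R_xlen_t)k * k * c;
      double* pgx = px + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          const double gv = pgo[oh + (R_xlen_t)Ho * ow];
          if (gv == 0.0) continue;
          for (int kj = 0; kj < k; ++kj) {
            const int iw = ow - pad + kj;
            if (iw < 0 || iw >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int ih = oh - pad + ki;
              if (ih >= 0 && ih < H)
                pgx[ih + (R_xlen_t)H * iw] += gv * pk[ki + k * kj];
            }
          }
        }
      }
    }
  }
  return gx;
}

// [[Rcpp::export(name = ".dwconv_bwd_weight_cpp")]]
NumericVector dwconv_bwd_weight_cpp(NumericVector x, NumericVector g,
                                    int k, int pad) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector dg = g.attr("dim");
  const int Ho = dg[0], Wo = dg[1];
  NumericVector gw((R_xlen_t)k * k * C);
  gw.attr("dim") = IntegerVector::create(k, k, C);
  const double* px = x.begin();
  const double* pg = g.begin();
  double* pw = gw.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* pim = px + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
      const double* pgo = pg + ((R_xlen_t)c + (R_xlen_t)C * n) * Ho * Wo;
      double* pk = pw + (R_xlen_t)k * k * c;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          double acc = 0.0;
          for (int ow = 0; ow < Wo; ++ow) {
            const int iw = ow - pad + kj;
            if (iw < 0 || iw >= W) continue;
            for (int oh = 0; oh < Ho; ++oh) {
              const int ih = oh - pad + ki;
              if (ih >= 0 && ih < H)
                acc += pim[ih + (R_xlen_t)H * iw] * pgo[oh + (R_xlen_t)Ho * ow];
            }
          }
          pk[ki + k * kj] += acc;
        }
      }
    }
  }
  return gw;
}

// Bilinear resize with half-pixel-center coordinate mapping:
// src = (dst + 0.5) * (in/out) - 0.5, clamped to the valid range.
// Constant images stay exactly constant under this convention.
// [[Rcpp::export(name = ".resize_bilinear_cpp")]]
NumericVector resize_bilinear_cpp(NumericVector x, int Ho, int Wo) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  const double* px = x.begin();
  double* py = y.begin();
  std::vector<int> h0(Ho), h1(Ho);
  std::vector<double> fh(Ho);
  for (int oh = 0; oh < Ho; ++oh) {
    double s = (oh + 0.5) * sh - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    h0[oh] = (int)std::floor(s);
    h1[oh] = std::min(h0[oh] + 1, H - 1);
    fh[oh] = s - h0[oh];
  }
  std::vector<int> w0(Wo), w1(Wo);
  std::vector<double> fw(Wo);
  for (int ow = 0; ow < Wo; ++ow) {
    double s = (ow + 0.5) * sw - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    w0[ow] = (int)std::floor(s);
    w1[ow] = std::min(w0[ow] + 1, W - 1);
    fw[ow] = s - w0[ow];
  }
  for (int cn = 0; cn < C * N; ++cn) {
    const double* pim = px + (R_xlen_t)cn * H * W;
    double* pout = py + (R_xlen_t)cn * Ho * Wo;
    for (int ow = 0; ow < Wo; ++ow) {
      const R_xlen_t c0 = (R_xlen_t)H * w0[ow], c1 = (R_xlen_t)H * w1[ow];
      for (int oh = 0; oh < Ho; ++oh) {
        const double a = pim[h0[oh] + c0] * (1 - fh[oh]) + pim[h1[oh] + c0] * fh[oh];
        const double b = pim[h0[oh] + c1] * (1 - fh[oh]) + pim[h1[oh] + c1] * fh[oh];
        pout[oh + (R_xlen_t)Ho * ow] = a * (1 - fw[ow]) + b * fw[ow];
      }
    }
  }
  return y;
}

// Adjoint of resize_bilinear (scatter-add with the same weights).
// [[Rcpp::export(name = ".resize_bilinear_adj_cpp")]]
NumericVector resize_bilinear_adj_cpp(NumericVector g, int H, int W) {
  IntegerVector d = g.attr("dim");
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector y((R_xlen_t)H * W * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  const double* pg = g.begin();
  double* py = y.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    const double* pgo = pg + (R_xlen_t)cn * Ho * Wo;
    double* pim = py + (R_xlen_t)cn * H * W;
    for (int ow = 0; ow < Wo; ++ow) {
      double s = (ow + 0.5) * sw - 0.5;
      if (s < 0) s = 0;
      if (s > W - 1) s = W - 1;
      const int iw0 = (int)std::floor(s), iw1 = std::min(iw0 + 1, W - 1);
      const double fw = s - iw0;
      for (int oh = 0; oh < Ho; ++oh) {
        double t = (oh + 0.5) * sh - 0.5;
        if (t < 0) t = 0;
        if (t > H - 1) t = H - 1;
        const int ih0 = (int)std::floor(t), ih1 = std::min(ih0 + 1, H - 1);
        const double fh = t - ih0;
        const double gv = pgo[oh + (R_xlen_t)Ho * ow];
        pim[ih0 + (R_xlen_t)H * iw0] += gv * (1 - fh) * (1 - fw);
        pim[ih1 + (R_xlen_t)H * iw0] += gv * fh * (1 - fw);
        pim[ih0 + (R_xlen_t)H * iw1] += gv * (1 - fh) * fw;
        pim[ih1 + (R_xlen_t)H * iw1] += gv * fh * fw;
      }
    }
  }
  return y;
}
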