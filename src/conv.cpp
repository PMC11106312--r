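// Fused convolution kernels (im2col + BLAS gemm + layout restore) so that
// the R layer never materializes the patch matrices or permutes arrays.
// Layout convention matches kernels.cpp: arrays are (H, W, C, N) col-major;
// weights (k, k, Cin, Cout); im2col rows ordered (oh, ow, n), columns
// (ki, kj, c).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_sz(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

static void im2col_fill(const double* px, int H, int W, int C, int N,
                        int k, int stride, int pad, arma::mat& cols) {
  const int Ho = out_sz(H, k, stride, pad), Wo = out_sz(W, k, stride, pad);
  const arma::uword nrow = (arma::uword)Ho * Wo * N;
  double* po = cols.memptr();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const arma::uword col = ki + (arma::uword)k * (kj + (arma::uword)k * c);
        double* pcol = po + col * nrow;
        int oh_lo = 0;
        while (oh_lo * stride - pad + ki < 0) ++oh_lo;
        int oh_hi = Ho - 1;
        while (oh_hi >= 0 && oh_hi * stride - pad + ki >= H) --oh_hi;
        for (int n = 0; n < N; ++n) {
          const double* pim = px + ((size_t)c + (size_t)C * n) * H * W;
          for (int ow = 0; ow < Wo; ++ow) {
            const int iw = ow * stride - pad + kj;
            double* prow = pcol + (size_t)Ho * (ow + (size_t)Wo * n);
            if (iw < 0 || iw >= W || oh_lo > oh_hi) {
              std::fill(prow, prow + Ho, 0.0);
              continue;
            }
            if (oh_lo > 0) std::fill(prow, prow + oh_lo, 0.0);
            if (oh_hi < Ho - 1) std::fill(prow + oh_hi + 1, prow + Ho, 0.0);
            const double* pin = pim + (size_t)H * iw - pad + ki;
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
}

static void col2im_add(const arma::mat& cols, int H, int W, int C, int N,
                       int k, int stride, int pad, double* px) {
  const int Ho = out_sz(H, k, stride, pad), Wo = out_sz(W, k, stride, pad);
  const arma::uword nrow = (arma::uword)Ho * Wo * N;
  const double* po = cols.memptr();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const arma::uword col = ki + (arma::uword)k * (kj + (arma::uword)k * c);
        const double* pcol = po + col * nrow;
        int oh_lo = 0;
        while (oh_lo * stride - pad + ki < 0) ++oh_lo;
        int oh_hi = Ho - 1;
        while (oh_hi >= 0 && oh_hi * stride - pad + ki >= H) --oh_hi;
        if (oh_lo > oh_hi) continue;
        for (int n = 0; n < N; ++n) {
          double* pim = px + ((size_t)c + (size_t)C * n) * H * W;
          for (int ow = 0; ow < Wo; ++ow) {
            const int iw = ow * stride - pad + kj;
            if (iw < 0 || iw >= W) continue;
            const double* prow = pcol + (size_t)Ho * (ow + (size_t)Wo * n);
            double* pout = pim + (size_t)H * iw - pad + ki;
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
}

// scatter (HoWoN x Cout) gemm result into (Ho, Wo, Cout, N) layout
static void mat_to_nchw(const arma::mat& ym, int Ho, int Wo, int Cout, int N,
                        double* py) {
  for (int co = 0; co < Cout; ++co) {
    const double* src = ym.colptr(co);
    for (int n = 0; n < N; ++n) {
      for (int ow = 0; ow < Wo; ++ow) {
        const double* s = src + (size_t)Ho * (ow + (size_t)Wo * n);
        double* d = py + (size_t)Ho * (ow + (size_t)Wo * (co + (size_t)Cout * n));
        std::copy(s, s + Ho, d);
      }
    }
  }
}

// gather (Ho, Wo, Cout, N) into (HoWoN x Cout)
static void nchw_to_mat(const double* py, int Ho, int Wo, int Cout, int N,
                        arma::mat& gm) {
  for (int co = 0; co < Cout; ++co) {
    double* dst = gm.colptr(co);
    for (int n = 0; n < N; ++n) {
      for (int ow = 0; ow < Wo; ++ow) {
        const double* s = py + (size_t)Ho * (ow + (size_t)Wo * (co + (size_t)Cout * n));
        double* d = dst + (size_t)Ho * (ow + (size_t)Wo * n);
        std::copy(s, s + Ho, d);
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd_cpp")]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector dw = w.attr("dim");
  const int k = dw[0], Cout = dw[3];
  const int Ho = out_sz(H, k, stride, pad), Wo = out_sz(W, k, stride, pad);
  arma::mat cols((arma::uword)Ho * Wo * N, (arma::uword)k * k * C);
  im2col_fill(x.begin(), H, W, C, N, k, stride, pad, cols);
  const arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)k * k * C,
                     Cout, false, true);
  arma::mat ym = cols * Wm;
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int co = 0; co < Cout; ++co) ym.col(co) += b[co];
  }
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  mat_to_nchw(ym, Ho, Wo, Cout, N, y.begin());
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd_cpp")]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gout,
                    int stride, int pad, bool want_gx) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector dw = w.attr("dim");
  const int k = dw[0], Cout = dw[3];
  const int Ho = out_sz(H, k, stride, pad), Wo = out_sz(W, k, stride, pad);
  arma::mat gm((arma::uword)Ho * Wo * N, Cout);
  nchw_to_mat(gout.begin(), Ho, Wo, Cout, N, gm);
  arma::mat cols((arma::uword)Ho * Wo * N, (arma::uword)k * k * C);
  im2col_fill(x.begin(), H, W, C, N, k, stride, pad, cols);
  arma::mat gwm = cols.t() * gm;
  cols.reset();
  NumericVector gw((R_xlen_t)k * k * C * Cout);
  gw.attr("dim") = IntegerVector::create(k, k, C, Cout);
  std::copy(gwm.begin(), gwm.end(), gw.begin());
  NumericVector gb(Cout);
  for (int co = 0; co < Cout; ++co) gb[co] = arma::accu(gm.col(co));
  List out = List::create(Named("gw") = gw, Named("gb") = gb);
  if (want_gx) {
    const arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)k * k * C,
                       Cout, false, true);
    arma::mat gcols = gm * Wm.t();
    NumericVector gx((R_xlen_t)H * W * C * N);
    gx.attr("dim") = IntegerVector::create(H, W, C, N);
    col2im_add(gcols, H, W, C, N, k, stride, pad, gx.begin());
    out["gx"] = gx;
  }
  return out;
}
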