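// Batched 2-d convolution via im2col + GEMM, with the matching backward
// pass. Shapes follow the package convention: inputs (H, W, C, B) and
// kernels (kh, kw, Cin, Cout), both column-major. Padding amounts are
// resolved by the R wrappers; the backward pass rebuilds the patch matrix
// from the cached input instead of storing it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void im2col_fill(const double* x, int h, int w, int ch, int kh, int kw,
                        int stride, int dil, int ph, int pw, int ho, int wo,
                        mat& cols) {
  for (int c = 0; c < ch; ++c) {
    const double* xc = x + (size_t)c * h * w;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        double* col = cols.colptr(ki + kh * (kj + kw * c));
        for (int ow = 0; ow < wo; ++ow) {
          const int ws = ow * stride + kj * dil - pw;
          double* dst = col + (size_t)ow * ho;
          if (ws < 0 || ws >= w) {
            std::fill(dst, dst + ho, 0.0);
            continue;
          }
          const double* src = xc + (size_t)ws * h;
          for (int oh = 0; oh < ho; ++oh) {
            const int hs = oh * stride + ki * dil - ph;
            dst[oh] = (hs < 0 || hs >= h) ? 0.0 : src[hs];
          }
        }
      }
    }
  }
}

static void col2im_add(const mat& cols, int h, int w, int ch, int kh, int kw,
                       int stride, int dil, int ph, int pw, int ho, int wo,
                       double* dx) {
  for (int c = 0; c < ch; ++c) {
    double* xc = dx + (size_t)c * h * w;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const double* col = cols.colptr(ki + kh * (kj + kw * c));
        for (int ow = 0; ow < wo; ++ow) {
          const int ws = ow * stride + kj * dil - pw;
          if (ws < 0 || ws >= w) continue;
          double* dst = xc + (size_t)ws * h;
          const double* src = col + (size_t)ow * ho;
          for (int oh = 0; oh < ho; ++oh) {
            const int hs = oh * stride + ki * dil - ph;
            if (hs >= 0 && hs < h) dst[hs] += src[oh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
Rcpp::NumericVector conv2d_fwd(const Rcpp::NumericVector& x,
                               const Rcpp::IntegerVector& xdim,
                               const Rcpp::NumericVector& w,
                               const Rcpp::IntegerVector& wdim,
                               const Rcpp::NumericVector& bias, int stride,
                               int dil, int ph, int pw, int ho, int wo) {
  const int h = xdim[0], wd = xdim[1], ch = xdim[2], nb = xdim[3];
  const int kh = wdim[0], kw = wdim[1], cout = wdim[3];
  const mat wm(const_cast<double*>(w.begin()), (size_t)kh * kw * ch, cout,
               false, true);
  const rowvec bv(const_cast<double*>(bias.begin()), cout, false, true);
  Rcpp::NumericVector out((size_t)ho * wo * cout * nb);
  out.attr("dim") = Rcpp::IntegerVector::create(ho, wo, cout, nb);
  mat cols((size_t)ho * wo, (size_t)kh * kw * ch);
  for (int b = 0; b < nb; ++b) {
    im2col_fill(x.begin() + (size_t)b * h * wd * ch, h, wd, ch, kh, kw,
                stride, dil, ph, pw, ho, wo, cols);
    mat y = cols * wm;
    y.each_row() += bv;
    std::copy(y.begin(), y.end(), out.begin() + (size_t)b * ho * wo * cout);
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
Rcpp::List conv2d_bwd(const Rcpp::NumericVector& x,
                      const Rcpp::IntegerVector& xdim,
                      const Rcpp::NumericVector& w,
                      const Rcpp::IntegerVector& wdim,
                      const Rcpp::NumericVector& dout, int stride, int dil,
                      int ph, int pw, int ho, int wo) {
  const int h = xdim[0], wd = xdim[1], ch = xdim[2], nb = xdim[3];
  const int kh = wdim[0], kw = wdim[1], cout = wdim[3];
  const mat wm(const_cast<double*>(w.begin()), (size_t)kh * kw * ch, cout,
               false, true);
  Rcpp::NumericVector dx((size_t)h * wd * ch * nb);
  dx.attr("dim") = xdim;
  mat dwm((size_t)kh * kw * ch, cout, fill::zeros);
  rowvec db(cout, fill::zeros);
  mat cols((size_t)ho * wo, (size_t)kh * kw * ch);
  for (int b = 0; b < nb; ++b) {
    im2col_fill(x.begin() + (size_t)b * h * wd * ch, h, wd, ch, kh, kw,
                stride, dil, ph, pw, ho, wo, cols);
    const mat dym(const_cast<double*>(dout.begin()) + (size_t)b * ho * wo * cout,
                  (size_t)ho * wo, cout, false, true);
    dwm += cols.t() * dym;
    db += sum(dym, 0);
    const mat dcols = dym * wm.t();
    col2im_add(dcols, h, wd, ch, kh, kw, stride, dil, ph, pw, ho, wo,
               dx.begin() + (size_t)b * h * wd * ch);
  }
  Rcpp::NumericVector dwv(dwm.begin(), dwm.end());
  dwv.attr("dim") = wdim;
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dwv,
                            Rcpp::Named("db") = Rcpp::NumericVector(db.begin(), db.end()));
}
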