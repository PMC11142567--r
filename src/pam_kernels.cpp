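// Chunked softmax position-attention kernels.
//
// The affinity matrix S = softmax_rows(Z B^T) is N x N with N = H * W
// (16384 rows for a 128 x 128 grid), so it is never materialized in full:
// both passes stream over row chunks, and the backward pass recomputes
// each chunk of S instead of caching it. The inner arithmetic runs in
// single precision, the working precision of this computation in
// practice; inputs and outputs are double.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static uword chunk_rows(uword n) {
  uword r = (1u << 25) / std::max<uword>(n, 1);
  if (r < 1) r = 1;
  if (r > n) r = n;
  return r;
}

// Row softmax in place, guarded by per-row max subtraction.
static void softmax_rows_inplace(fmat& lg) {
  fvec mx = max(lg, 1);
  lg.each_col() -= mx;
  lg = exp(lg);
  fvec rs = sum(lg, 1);
  lg.each_col() /= rs;
}

// [[Rcpp::export(name = ".pam_attention_forward")]]
Rcpp::NumericMatrix pam_attention_forward(const Rcpp::NumericMatrix& z,
                                          const Rcpp::NumericMatrix& b,
                                          const Rcpp::NumericMatrix& d) {
  const fmat zf = conv_to<fmat>::from(mat(z.begin(), z.nrow(), z.ncol()));
  const fmat bf = conv_to<fmat>::from(mat(b.begin(), b.nrow(), b.ncol()));
  const fmat df = conv_to<fmat>::from(mat(d.begin(), d.nrow(), d.ncol()));
  const uword n = zf.n_rows;
  fmat att(n, df.n_cols);
  const uword cs = chunk_rows(n);
  for (uword j0 = 0; j0 < n; j0 += cs) {
    const uword j1 = std::min(n - 1, j0 + cs - 1);
    fmat s = zf.rows(j0, j1) * bf.t();
    softmax_rows_inplace(s);
    att.rows(j0, j1) = s * df;
  }
  const mat out = conv_to<mat>::from(att);
  return Rcpp::wrap(out);
}

// [[Rcpp::export(name = ".pam_attention_backward")]]
Rcpp::List pam_attention_backward(const Rcpp::NumericMatrix& z,
                                  const Rcpp::NumericMatrix& b,
                                  const Rcpp::NumericMatrix& d,
                                  const Rcpp::NumericMatrix& da) {
  const fmat zf = conv_to<fmat>::from(mat(z.begin(), z.nrow(), z.ncol()));
  const fmat bf = conv_to<fmat>::from(mat(b.begin(), b.nrow(), b.ncol()));
  const fmat df = conv_to<fmat>::from(mat(d.begin(), d.nrow(), d.ncol()));
  const fmat daf = conv_to<fmat>::from(mat(da.begin(), da.nrow(), da.ncol()));
  const uword n = zf.n_rows;
  fmat dz(n, zf.n_cols, fill::zeros);
  fmat db(n, bf.n_cols, fill::zeros);
  fmat dd(n, df.n_cols, fill::zeros);
  const uword cs = chunk_rows(n);
  for (uword j0 = 0; j0 < n; j0 += cs) {
    const uword j1 = std::min(n - 1, j0 + cs - 1);
    fmat s = zf.rows(j0, j1) * bf.t();
    softmax_rows_inplace(s);
    const fmat da_j = daf.rows(j0, j1);
    fmat ds = da_j * df.t();
    const fvec t = sum(ds % s, 1);
    ds %= s;                 // now holds s .* dS
    ds -= s.each_col() % t;  // softmax Jacobian: s .* (dS - rowsum)
    dz.rows(j0, j1) = ds * bf;
    db += ds.t() * zf.rows(j0, j1);
    dd += s.t() * da_j;
  }
  return Rcpp::List::create(
      Rcpp::Named("dz") = Rcpp::wrap(conv_to<mat>::from(dz)),
      Rcpp::Named("db") = Rcpp::wrap(conv_to<mat>::from(db)),
      Rcpp::Named("dd") = Rcpp::wrap(conv_to<mat>::from(dd)));
}
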