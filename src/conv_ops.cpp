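// 3x3 convolution on zero-padded, pixel-major feature matrices.
//
// Feature maps are (B * Hp * Wp) x C matrices: samples stacked, column-major
// within a sample, with a one-pixel zero border around every sample (Hp =
// H + 2, Wp = W + 2). With that layout the nine kernel taps are plain row
// shifts (offset o = dc * Hp + dr), so the convolution is nine contiguous
// submatrix GEMMs — no gather, near-BLAS speed. Border rows of the output
// accumulate seam garbage and are zeroed before returning (`bidx`, 1-based);
// the zero-border invariant of the inputs makes everything else exact.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline void zero_rows(mat& M, const arma::uvec& bidx) {
  for (uword i = 0; i < bidx.n_elem; ++i) M.row(bidx[i] - 1).zeros();
}

// [[Rcpp::export]]
arma::mat conv3p_fw(const arma::mat& X, const arma::mat& W,
                    const arma::rowvec& b, const int Hp,
                    const arma::uvec& bidx) {
  const uword n = X.n_rows, Cin = X.n_cols, Cout = W.n_cols;
  mat Y(n, Cout, fill::zeros);
  for (int k = 0; k < 9; ++k) {
    const int dc = k / 3 - 1, dr = k % 3 - 1;
    const int o = dc * Hp + dr;
    const uword a = static_cast<uword>(std::max(0, -o));
    const uword z = n - 1 - static_cast<uword>(std::max(0, o));
    Y.rows(a, z) += X.rows(a + o, z + o) *
      W.rows(static_cast<uword>(k) * Cin, static_cast<uword>(k) * Cin + Cin - 1);
  }
  Y.each_row() += b;
  zero_rows(Y, bidx);
  return Y;
}

// dY must already have zero border rows.
// [[Rcpp::export]]
Rcpp::List conv3p_bw(const arma::mat& dY, const arma::mat& X,
                     const arma::mat& W, const int Hp) {
  const uword n = X.n_rows, Cin = X.n_cols;
  mat dX(n, Cin, fill::zeros);
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  for (int k = 0; k < 9; ++k) {
    const int dc = k / 3 - 1, dr = k % 3 - 1;
    const int o = dc * Hp + dr;
    const uword a = static_cast<uword>(std::max(0, -o));
    const uword z = n - 1 - static_cast<uword>(std::max(0, o));
    const uword r0 = static_cast<uword>(k) * Cin;
    dX.rows(a + o, z + o) += dY.rows(a, z) * W.rows(r0, r0 + Cin - 1).t();
    dW.rows(r0, r0 + Cin - 1) = X.rows(a + o, z + o).t() * dY.rows(a, z);
  }
  rowvec db = sum(dY, 0);
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
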