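// Hot loop of the phase-randomization permutation test.
//
// A phase surrogate keeps every row's full amplitude spectrum, hence also
// its mean (DC bin) and variance (Parseval). The Pearson matrix of a
// surrogate set can therefore be assembled in the frequency domain from
// the rotated positive-frequency FFT block plus the constant DC/Nyquist
// contribution, with centering and scaling terms precomputed once. This is
// algebraically identical to scramble -> inverse FFT -> cor() and is
// asserted against that path in the test suite.
//
// Phases are drawn from R's RNG (column-major, matching runif(half * N)
// in R) so results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::imat surrogate_exceed_counts(const arma::cx_mat& fpos,
                                   const arma::mat& base,
                                   const arma::mat& robs_abs,
                                   const arma::vec& col_means,
                                   const arma::vec& col_sds,
                                   const int t_len,
                                   const int n_surrogates) {
  const arma::uword half = fpos.n_rows;
  const arma::uword n = fpos.n_cols;
  arma::imat cnt(n, n, arma::fill::zeros);
  const arma::mat denom = (t_len - 1.0) * (col_sds * col_sds.t());
  const arma::mat meanterm = static_cast<double>(t_len) *
    (col_means * col_means.t());
  arma::cx_mat fs(half, n);

  for (int s = 0; s < n_surrogates; ++s) {
    for (arma::uword j = 0; j < n; ++j) {
      for (arma::uword i = 0; i < half; ++i) {
        const double ph = R::runif(0.0, 2.0 * M_PI);
        fs(i, j) = fpos(i, j) * std::complex<double>(std::cos(ph),
                                                     std::sin(ph));
      }
    }
    // fs.t() is the conjugate transpose: Hermitian cross-products
    const arma::mat cp = (base + 2.0 * arma::real(fs.t() * fs)) /
      static_cast<double>(t_len);
    const arma::mat r = arma::abs((cp - meanterm) / denom);
    cnt += arma::conv_to<arma::imat>::from(r >= robs_abs);
  }
  return cnt;
}
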