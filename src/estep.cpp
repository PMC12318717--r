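// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Zero-mean Gaussian log densities for all rows of X under each state
// covariance. Cholesky factorisation and the quadratic form are fused
// here to avoid large R-level temporaries in the EM inner loop.
// [[Rcpp::export(name = ".gauss_logdens_cpp")]]
arma::mat gauss_logdens_cpp(const arma::mat& X, const List& covs) {
  const int K = covs.size();
  const arma::uword d = X.n_cols;
  arma::mat out(X.n_rows, K);
  const double c0 = d * std::log(2.0 * M_PI);
  for (int k = 0; k < K; ++k) {
    arma::mat S = as<arma::mat>(covs[k]);
    arma::mat R;
    if (!arma::chol(R, S))
      stop("state %d covariance is not positive definite", k + 1);
    double logdet = 2.0 * arma::sum(arma::log(R.diag()));
    // q = rowSums((X R^{-1})^2); triangular solve once
    arma::mat U = arma::solve(arma::trimatu(R), arma::eye(d, d));
    arma::mat V = X * U;
    out.col(k) = -0.5 * (c0 + logdet + arma::sum(arma::square(V), 1));
  }
  return out;
}

// Posterior-weighted scatter matrices: S_k = X' diag(gamma_k) X.
// [[Rcpp::export(name = ".weighted_scatter_cpp")]]
arma::cube weighted_scatter_cpp(const arma::mat& X, const arma::mat& gamma) {
  const arma::uword d = X.n_cols, K = gamma.n_cols;
  arma::cube out(d, d, K);
  for (arma::uword k = 0; k < K; ++k) {
    arma::mat Xw = X.each_col() % arma::sqrt(gamma.col(k));
    out.slice(k) = Xw.t() * Xw;
  }
  return out;
}
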