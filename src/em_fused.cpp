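// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// One fused EM iteration for the zero-mean Gaussian HMM over a
// concatenated data matrix with subject boundaries. Computes the log
// observation densities, runs the scaled forward-backward per subject,
// and accumulates the M-step statistics, all in two passes over the
// data -- the pipeline's inner loop is memory-bound, so avoiding the
// R-level temporaries matters more than the flop count.
//
// Arguments: X (T x d), list of d x d covariances, A (K x K), pi (K),
// starts/ends 1-based subject boundaries.
// Returns: loglik, xi (K x K), pi_acc (K), scatter cube (d x d x K),
// gamma column sums.
// [[Rcpp::export(name = ".em_iteration_cpp")]]
List em_iteration_cpp(const arma::mat& X, const List& covs,
                      const arma::mat& A, const arma::vec& pi0,
                      const IntegerVector& starts,
                      const IntegerVector& ends) {
  const arma::uword T = X.n_rows, d = X.n_cols;
  const int K = covs.size();
  const double c0 = d * std::log(2.0 * M_PI);

  // per-state inverse Cholesky factors and log-determinants
  std::vector<arma::mat> Rinv(K);
  arma::vec logdet(K);
  for (int k = 0; k < K; ++k) {
    arma::mat R;
    if (!arma::chol(R, as<arma::mat>(covs[k])))
      stop("state %d covariance is not positive definite", k + 1);
    logdet[k] = 2.0 * arma::sum(arma::log(R.diag()));
    Rinv[k] = arma::solve(arma::trimatu(R), arma::eye(d, d));
  }

  // pass 1: log densities (blocked to keep the working set small)
  arma::mat logB(T, K);
  const arma::uword blk = 65536;
  for (arma::uword r0 = 0; r0 < T; r0 += blk) {
    const arma::uword r1 = std::min(r0 + blk, T) - 1;
    const arma::mat Xb = X.rows(r0, r1);
    for (int k = 0; k < K; ++k) {
      arma::mat V = Xb * Rinv[k];
      logB.submat(r0, k, r1, k) =
        -0.5 * (c0 + logdet[k] + arma::sum(arma::square(V), 1));
    }
  }

  // forward-backward per subject (scaled, linear space)
  arma::mat gamma(T, K);
  arma::mat xi(K, K, arma::fill::zeros);
  arma::vec pi_acc(K, arma::fill::zeros);
  double loglik = 0.0;
  const int n_seq = starts.size();
  for (int s = 0; s < n_seq; ++s) {
    const arma::uword a0 = starts[s] - 1, a1 = ends[s] - 1;
    const arma::uword n = a1 - a0 + 1;
    arma::mat B(n, K), alpha(n, K), beta(n, K);
    arma::vec cs(n), bmax(n);
    for (arma::uword t = 0; t < n; ++t) {
      double m = logB(a0 + t, 0);
      for (int k = 1; k < K; ++k) m = std::max(m, logB(a0 + t, k));
      bmax[t] = m;
      for (int k = 0; k < K; ++k)
        B(t, k) = std::exp(logB(a0 + t, k) - m);
    }
    double z = 0.0;
    for (int k = 0; k < K; ++k) {
      alpha(0, k) = pi0[k] * B(0, k);
      z += alpha(0, k);
    }
    if (z <= 0) stop("forward pass underflow");
    cs[0] = z;
    for (int k = 0; k < K; ++k) alpha(0, k) /= z;
    for (arma::uword t = 1; t < n; ++t) {
      z = 0.0;
      for (int k = 0; k < K; ++k) {
        double acc = 0.0;
        for (int j = 0; j < K; ++j) acc += alpha(t - 1, j) * A(j, k);
        acc *= B(t, k);
        alpha(t, k) = acc;
        z += acc;
      }
      if (z <= 0) stop("forward pass underflow");
      cs[t] = z;
      for (int k = 0; k < K; ++k) alpha(t, k) /= z;
    }
    for (int k = 0; k < K; ++k) beta(n - 1, k) = 1.0;
    for (int t = n - 2; t >= 0; --t)
      for (int j = 0; j < K; ++j) {
        double acc = 0.0;
        for (int k = 0; k < K; ++k)
          acc += A(j, k) * B(t + 1, k) * beta(t + 1, k);
        beta(t, j) = acc / cs[t + 1];
      }
    for (arma::uword t = 0; t < n; ++t) {
      double g = 0.0;
      for (int k = 0; k < K; ++k) {
        gamma(a0 + t, k) = alpha(t, k) * beta(t, k);
        g += gamma(a0 + t, k);
      }
      for (int k = 0; k < K; ++k) gamma(a0 + t, k) /= g;
    }
    for (arma::uword t = 0; t + 1 < n; ++t) {
      const double z1 = cs[t + 1];
      for (int j = 0; j < K; ++j) {
        const double aj = alpha(t, j);
        for (int k = 0; k < K; ++k)
          xi(j, k) += aj * A(j, k) * B(t + 1, k) * beta(t + 1, k) / z1;
      }
    }
    for (int k = 0; k < K; ++k) pi_acc[k] += gamma(a0, k);
    for (arma::uword t = 0; t < n; ++t) loglik += std::log(cs[t]) + bmax[t];
  }

  // pass 2: posterior-weighted scatters, one read of X
  arma::cube scat(d, d, K, arma::fill::zeros);
  arma::vec g_tot(K, arma::fill::zeros);
  for (arma::uword r0 = 0; r0 < T; r0 += blk) {
    const arma::uword r1 = std::min(r0 + blk, T) - 1;
    const arma::mat Xb = X.rows(r0, r1);
    for (int k = 0; k < K; ++k) {
      arma::vec w = arma::sqrt(gamma.submat(r0, k, r1, k));
      arma::mat Xw = Xb.each_col() % w;
      scat.slice(k) += Xw.t() * Xw;
      g_tot[k] += arma::accu(arma::square(w));
    }
  }

  return List::create(_["loglik"] = loglik, _["xi"] = xi,
                      _["pi_acc"] = pi_acc, _["scatter"] = scat,
                      _["g_tot"] = g_tot);
}
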