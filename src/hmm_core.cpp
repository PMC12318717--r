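#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a discrete-state HMM given per-sample
// log observation densities. Returns posteriors (gamma), the summed
// expected transition counts (xi) and the data log-likelihood.
//
// logB: T x K log observation densities
// logA: K x K log transition matrix
// logpi: K log initial distribution
// [[Rcpp::export(name = ".forward_backward_cpp")]]
List forward_backward_cpp(NumericMatrix logB, NumericMatrix logA,
                          NumericVector logpi) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  NumericMatrix A(K, K);
  NumericVector c(T);          // per-step scaling constants
  NumericMatrix B(T, K);       // scaled observation likelihoods
  NumericVector bmax(T);

  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    bmax[t] = m;
    for (int k = 0; k < K; ++k) B(t, k) = std::exp(logB(t, k) - m);
  }
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) A(i, j) = std::exp(logA(i, j));

  // forward pass
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = std::exp(logpi[k]) * B(0, k);
    s += alpha(0, k);
  }
  if (s <= 0) stop("forward pass underflow at t = 1");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      a *= B(t, k);
      alpha(t, k) = a;
      s += a;
    }
    if (s <= 0) stop("forward pass underflow at t = %d", t + 1);
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }

  // backward pass (scaled by the same constants)
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double b = 0.0;
      for (int k = 0; k < K; ++k) b += A(j, k) * B(t + 1, k) * beta(t + 1, k);
      beta(t, j) = b / c[t + 1];
    }
  }

  // posteriors
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      g += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  // expected transition counts, summed over t
  NumericMatrix xi(K, K);
  for (int t = 0; t < T - 1; ++t) {
    double z = c[t + 1];
    for (int j = 0; j < K; ++j) {
      double aj = alpha(t, j);
      for (int k = 0; k < K; ++k)
        xi(j, k) += aj * A(j, k) * B(t + 1, k) * beta(t + 1, k) / z;
    }
  }

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(c[t]) + bmax[t];

  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["loglik"] = loglik);
}

// Sample a Markov chain of length n from transition matrix P (rows) and
// initial distribution init, consuming pre-drawn uniforms u (length n) so
// that reproducibility is governed by R's RNG.
// [[Rcpp::export(name = ".sample_markov_cpp")]]
IntegerVector sample_markov_cpp(NumericMatrix P, NumericVector init,
                                NumericVector u) {
  const int n = u.size(), K = P.ncol();
  IntegerVector out(n);
  int state = K - 1;
  double acc = 0.0;
  for (int k = 0; k < K; ++k) {
    acc += init[k];
    if (u[0] <= acc) { state = k; break; }
  }
  out[0] = state + 1;
  for (int t = 1; t < n; ++t) {
    acc = 0.0;
    int next = K - 1;
    for (int k = 0; k < K; ++k) {
      acc += P(state, k);
      if (u[t] <= acc) { next = k; break; }
    }
    state = next;
    out[t] = state + 1;
  }
  return out;
}

// Maximum a-posteriori state sequence (Viterbi) in log space.
// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(NumericMatrix logB, NumericMatrix logA,
                          NumericVector logpi) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericVector delta(K), nxt(K);
  IntegerMatrix back(T, K);
  for (int k = 0; k < K; ++k) delta[k] = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = delta[0] + logA(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = delta[j] + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      back(t, k) = arg;
      nxt[k] = best + logB(t, k);
    }
    delta = clone(nxt);
  }
  IntegerVector path(T);
  int arg = 0;
  for (int k = 1; k < K; ++k) if (delta[k] > delta[arg]) arg = k;
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = back(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}

// Time-delay embedding: row t of the output holds parcel values at
// lags -L..L around sample t (parcel-blocked columns). Pure copying;
// kept in compiled code because the R indexing loop dominates the
// pipeline runtime on large cohorts.
// [[Rcpp::export(name = ".tde_embed_cpp")]]
NumericMatrix tde_embed_cpp(NumericMatrix x, int L) {
  const int T = x.nrow(), P = x.ncol();
  const int n_out = T - 2 * L, W = 2 * L + 1;
  NumericMatrix out(n_out, W * P);
  for (int p = 0; p < P; ++p) {
    for (int l = -L; l <= L; ++l) {
      const int col = p * W + (l + L);
      const double* src = &x(L + l, p);
      double* dst = &out(0, col);
      std::copy(src, src + n_out, dst);
    }
  }
  return out;
}
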