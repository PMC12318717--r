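test_that("time-delay embedding has the documented geometry", {
  x <- matrix(rnorm(1000 * 39), 1000, 39)
  E <- tde_embed(x, lags = 7)
  expect_equal(dim(E), c(986, 585))
  # row t holds parcel values at t-L..t+L
  expect_equal(E[1, 1:15], x[1:15, 1])
  expect_equal(E[10, 16:30], x[10:24, 2])
  expect_true(all(apply(tde_embed(matrix(1, 100, 2), 3), 2, sd) == 0))
  expect_error(tde_embed(matrix(0, 10, 2), lags = 7), "shorter")
})

test_that("white-noise embedded columns are uncorrelated off the diagonal", {
  set.seed(20)
  E <- tde_embed(cbind(rnorm(20000)), lags = 3)
  C <- cor(E)
  expect_lt(max(abs(C[upper.tri(C)])), 0.05)
})

test_that("PCA reduction is exact on low-rank data and orders variance", {
  set.seed(21)
  basis <- matrix(rnorm(10 * 2), 2, 10)
  X <- matrix(rnorm(500 * 2), 500, 2) %*% basis +
    matrix(rnorm(5000, sd = 1e-8), 500, 10)
  p <- pca_reduce(scale(X), 2)
  expect_gt(sum(p$explained), 1 - 1e-6)
  full <- pca_reduce(matrix(rnorm(4000), 200, 20), 10)
  expect_true(all(diff(full$eigenvalues) <= 1e-10))
  # reconstruction error from k components = sum of discarded eigenvalues
  Y <- matrix(rnorm(300 * 6), 300, 6)
  pr <- pca_reduce(Y, 3)
  Z <- sweep(sweep(Y, 2, pr$center), 2, pr$scale, "/")
  recon <- pr$scores %*% t(pr$rotation)
  err <- sum((Z - recon)^2) / (nrow(Y) - 1)
  expect_equal(err, sum(pr$eigenvalues[4:6]), tolerance = 1e-8)
  expect_error(pca_reduce(Y, 10), "exceeds")
})

test_that("forward-backward matches exhaustive path enumeration", {
  set.seed(22)
  for (trial in 1:6) {
    K <- sample(2:3, 1)
    T <- sample(4:8, 1)
    d <- 2
    X <- matrix(rnorm(T * d), T, d)
    covs <- lapply(seq_len(K), function(k) {
      A <- matrix(rnorm(d * d), d)
      crossprod(A) / d + diag(d) * 0.5
    })
    A <- matrix(runif(K * K) + 0.2, K)
    A <- A / rowSums(A)
    pi0 <- rep(1 / K, K)
    logB <- burstnet:::gaussian_logdens(X, covs)
    fb <- burstnet:::.forward_backward_cpp(logB, log(A), log(pi0))
    gamma_oracle <- enumerate_posteriors(X, covs, A, pi0)
    expect_lt(max(abs(fb$gamma - gamma_oracle)), 1e-10)
    # log-likelihood against direct summation
    expect_true(all(abs(rowSums(fb$gamma) - 1) < 1e-12))
  }
})

test_that("K = 1 fit equals the closed-form Gaussian evidence", {
  set.seed(23)
  X <- matrix(rnorm(2000 * 3), 2000, 3)
  f <- fit_hmm(X, K = 1, seed = 1, max_iter = 10)
  S <- crossprod(X) / nrow(X)                     # zero-mean MLE scatter
  d <- 3
  ll <- -0.5 * nrow(X) * (d * log(2 * pi) + determinant(S)$modulus[1]) -
    0.5 * sum(diag(solve(S) %*% crossprod(X)))
  expect_equal(f$free_energy, -ll, tolerance = 1e-6)
  sp <- state_timecourses(f, X, lags = 0, fs = 100)
  expect_true(all(sp$gamma == 1))
})

test_that("EM objective is monotone and rows stay stochastic", {
  set.seed(24)
  co <- distinct_state_cohort(n_sub = 2, dur = 15)
  ts_list <- lapply(co$subjects, function(s) zscore_parcels(s$ts))
  h <- tde_hmm(ts_list, K = 2, n_runs = 1, max_iter = 15)
  tr <- h$fit$trace
  expect_true(all(diff(tr) <= 1e-6 * abs(tr[-length(tr)])))
  expect_true(all(abs(rowSums(h$fit$A) - 1) < 1e-8))
  for (sp in h$posteriors)
    expect_true(all(abs(rowSums(sp$gamma) - 1) < 1e-8))
})

test_that("free energy is invariant to state relabelling", {
  set.seed(25)
  X <- matrix(rnorm(1500 * 4), 1500, 4)
  f <- fit_hmm(X, K = 3, seed = 2, max_iter = 8)
  perm <- c(3, 1, 2)
  f2 <- f
  f2$A <- f$A[perm, perm]
  f2$pi <- f$pi[perm]
  f2$covs <- f$covs[perm]
  ll1 <- state_timecourses(f, X, lags = 0)$loglik
  ll2 <- state_timecourses(f2, X, lags = 0)$loglik
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("run selection takes lowest free energy, ties to lowest seed", {
  mk <- function(fe, seed) structure(list(free_energy = fe, seed = seed,
                                          K = 2), class = "hmm_fit")
  expect_equal(select_best_run(list(mk(10, 1), mk(7, 2), mk(12, 3)))$seed, 2)
  expect_equal(select_best_run(list(mk(7, 3), mk(7, 1)))$seed, 1)
  expect_equal(select_best_run(list(mk(5, 9)))$seed, 9)
  expect_error(select_best_run(list(mk(5, 1),
                                    structure(list(free_energy = 4,
                                                   seed = 2, K = 3),
                                              class = "hmm_fit"))),
               "mix")
})

test_that("posterior padding realigns with the recording", {
  set.seed(26)
  X <- matrix(rnorm(500 * 3), 500, 3)
  f <- fit_hmm(X, K = 2, seed = 1, max_iter = 5)
  sp <- state_timecourses(f, X, lags = 7, fs = 100)
  expect_equal(nrow(sp$gamma), 514)
  expect_equal(sum(sp$padded), 14)
  expect_true(all(abs(rowSums(sp$gamma) - 1) < 1e-8))
})

test_that("state metrics partition occupancy and count hand-built paths", {
  gamma <- matrix(0, 100, 2)
  path <- rep(c(1L, 2L), 50)
  gamma[cbind(seq_len(100), path)] <- 1
  sp <- structure(list(gamma = gamma, path = path,
                       padded = rep(FALSE, 100), fs = 250, K = 2),
                  class = "state_probs")
  sm <- state_metrics(sp)
  expect_equal(sm$fo, c(0.5, 0.5))
  expect_equal(sm$mean_lifetime, c(0.004, 0.004))
  expect_equal(sm$rate, c(125, 125))
  expect_equal(sum(sm$fo), 1)
})

test_that("distinct spectral states are recovered from the signal", {
  co <- distinct_state_cohort(n_sub = 4, dur = 30, seed = 31)
  ts_list <- lapply(co$subjects, function(s) zscore_parcels(s$ts))
  h <- tde_hmm(ts_list, K = 3, n_runs = 2, max_iter = 30)
  agree <- label_agreement(co, h)
  expect_gt(mean(agree), 0.85)
  # recovered FO close to planted after matching
  i <- 1
  planted <- co$subjects[[i]]$states
  onehot <- outer(planted, 1:3, "==") * 1
  m <- match_states(onehot, h$posteriors[[i]]$gamma)
  met <- state_metrics(h$posteriors[[i]])
  for (k in 1:3)
    expect_lt(abs(met$fo[m[k]] - mean(planted == k)), 0.05)
})

test_that("state spectra changes centre at zero and flag empty states", {
  co <- distinct_state_cohort(n_sub = 2, dur = 20, seed = 33)
  ts <- zscore_parcels(co$subjects[[1]]$ts)
  ts_list <- list(ts, zscore_parcels(co$subjects[[2]]$ts))
  h <- tde_hmm(ts_list, K = 2, n_runs = 1, max_iter = 10)
  ss <- state_spectra(ts, h$posteriors[[1]])
  centred <- apply(ss$power_change, c(1, 2), mean)
  expect_lt(max(abs(centred)), 1e-10)
  bc <- state_beta_power_change(ss, 1:2)
  expect_length(bc, 2)
  expect_equal(sum(bc), 0, tolerance = 1e-10)
})
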