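# Shared fixtures and independent oracle implementations used across
# the suite. Oracles deliberately avoid the package's own computation
# paths.

sine_ts <- function(freq, fs = 250, dur = 20, amp = 1, n_extra = 0,
                    noise = 0) {
  t0 <- seq_len(fs * dur) / fs
  x <- amp * sin(2 * pi * freq * t0)
  m <- cbind(x)
  if (n_extra > 0)
    m <- cbind(m, matrix(rnorm(length(t0) * n_extra), ncol = n_extra))
  if (noise > 0) m <- m + rnorm(length(m), sd = noise)
  parcel_ts(m, fs)
}

random_track <- function(n, p = 0.3, fs = 100) {
  binary_track(runif(n) < p, fs)
}

# brute-force HMM posteriors by enumerating all K^T state paths with
# zero-mean Gaussian emissions
enumerate_posteriors <- function(X, covs, A, pi0) {
  T <- nrow(X); K <- length(covs)
  dens <- sapply(seq_len(K), function(k)
    mvtnorm_dens(X, covs[[k]]))
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  w <- apply(paths, 1, function(s) {
    lp <- log(pi0[s[1]]) + log(dens[1, s[1]])
    if (T > 1) for (t in 2:T)
      lp <- lp + log(A[s[t - 1], s[t]]) + log(dens[t, s[t]])
    exp(lp)
  })
  w <- w / sum(w)
  gamma <- matrix(0, T, K)
  for (t in seq_len(T))
    for (k in seq_len(K))
      gamma[t, k] <- sum(w[paths[, t] == k])
  gamma
}

# plain zero-mean multivariate normal density (no shared code with the
# package's cholesky path)
mvtnorm_dens <- function(X, S) {
  d <- ncol(X)
  Si <- solve(S)
  q <- rowSums((X %*% Si) * X)
  exp(-0.5 * q) / sqrt((2 * pi)^d * det(S))
}

# segment-wise multitaper oracle: direct tapered periodogram averaged
# over the windows listed in `wins` (window indices, 1-based,
# non-overlapping windows of length wl)
oracle_segment_psd <- function(x, fs, wl, wins, n_tapers = 7, nw = 4) {
  W <- nw / wl
  t0 <- seq_len(wl) - 1
  Amat <- matrix(0, wl, wl)
  diag(Amat) <- ((wl - 1 - 2 * t0) / 2)^2 * cos(2 * pi * W)
  off <- (t0[-1] * (wl - t0[-1])) / 2
  Amat[cbind(seq_len(wl - 1), 2:wl)] <- off
  Amat[cbind(2:wl, seq_len(wl - 1))] <- off
  tap <- eigen(Amat, symmetric = TRUE)$vectors[, seq_len(n_tapers)]
  tap <- tap * rep(1 / sqrt(colSums(tap^2)), each = wl)
  nf <- wl %/% 2 + 1
  acc <- numeric(nf)
  for (w in wins) {
    seg <- x[((w - 1) * wl + 1):(w * wl)]
    for (j in seq_len(n_tapers)) {
      X <- fft(seg * tap[, j])[seq_len(nf)]
      acc <- acc + Mod(X)^2
    }
  }
  psd <- acc * 2 / (fs * n_tapers * length(wins))
  list(freq = (seq_len(nf) - 1) * fs / wl, psd = psd)
}

# Grubbs two-sided critical value (closed form), the max_outliers = 1
# special case of GESD
grubbs_crit <- function(n, alpha = 0.05) {
  tq <- qt(1 - alpha / (2 * n), n - 2)
  (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
}

# small 3-state cohort with spectrally distinct states, shared by the
# HMM recovery tests
distinct_state_cohort <- function(n_sub = 5, dur = 30, amp = 2.5,
                                  lifetime = 0.1, seed = 3) {
  sigs <- list(
    state_signature(10, 4, c(1, 1, 0.3, 0, 0), amplitude = amp),
    state_signature(20, 6, c(0, 0.3, 1, 1, 0), amplitude = amp),
    state_signature(35, 8, c(0, 0, 0.3, 1, 1), amplitude = amp))
  spec <- cohort_spec(n_hc = n_sub - 1, n_pd = 1, n_parcels = 5,
                      duration = dur, n_states = 3,
                      mean_lifetime = lifetime, pd_fo_scale = 1,
                      signatures = sigs, subject_jitter_sd = 0,
                      seed = seed)
  generate_cohort(spec)
}

label_agreement <- function(cohort, hmm) {
  vapply(seq_along(cohort$subjects), function(i) {
    planted <- cohort$subjects[[i]]$states
    K <- max(planted)
    onehot <- outer(planted, seq_len(K), "==") * 1
    m <- match_states(onehot, hmm$posteriors[[i]]$gamma)
    v <- !hmm$posteriors[[i]]$padded
    mean((m[planted])[v] == hmm$posteriors[[i]]$path[v])
  }, numeric(1))
}
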