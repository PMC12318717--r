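test_that("Welch spectrum locates a pure tone and conserves power", {
  ts <- sine_ts(20, fs = 250, dur = 20)
  ps <- welch_psd(zscore_parcels(ts))
  expect_equal(ps$freq[which.max(ps$power[, 1])], 20)
  expect_equal(diff(ps$freq[1:2]), 0.5)          # 500-sample window @250 Hz
  # zero signal -> zero power (unscored)
  z <- parcel_ts(cbind(rep(0, 2000)), 250)
  expect_true(all(welch_psd(z)$power == 0))
  # Parseval: integrated relative power of z-scored noise ~ 1
  set.seed(3)
  wn <- zscore_parcels(parcel_ts(cbind(rnorm(25000)), 250))
  ps2 <- welch_psd(wn)
  expect_lt(abs(sum(ps2$power[, 1]) * 0.5 - 1), 0.02)
})

test_that("motor band power averages parcels and bins", {
  ps <- structure(list(freq = seq(0, 40, 0.5),
                       power = matrix(1, 81, 2)), class = "power_spectrum")
  expect_equal(motor_band_power(ps, 1:2, c(16, 25.5)), 1)
  ps$power[, 1] <- 2; ps$power[, 2] <- 4
  expect_equal(motor_band_power(ps, 1:2, c(16, 25.5)), 3)
  expect_error(motor_band_power(ps, 1:2, c(100, 110)), "no frequency bins")
})

test_that("band power responds to an in-band peak", {
  set.seed(4)
  flat <- zscore_parcels(parcel_ts(cbind(rnorm(10000), rnorm(10000)), 250))
  peaky <- zscore_parcels(parcel_ts(
    flat$data + cbind(2 * sin(2 * pi * 20 * seq_len(10000) / 250), 0), 250))
  expect_gt(motor_band_power(welch_psd(peaky), 1, c(16, 25.5)),
            motor_band_power(welch_psd(flat), 1, c(16, 25.5)))
})

test_that("DPSS tapers are orthonormal and concentrated", {
  tap <- burstnet:::dpss_tapers(500, 7, 4)
  expect_equal(crossprod(tap), diag(7), tolerance = 1e-8)
  # leading taper concentrates energy in |f| <= W
  h <- Mod(fft(c(tap[, 1], rep(0, 3500))))^2
  inband <- sum(h[1:33]) / sum(h[1:2000])        # W = 4/500 -> bin 32 @ df=1/4000
  expect_gt(inband, 0.99)
})

test_that("multitaper with unit weights matches the unweighted estimate", {
  set.seed(5)
  ts <- parcel_ts(matrix(rnorm(6000), 3000, 2), 250)
  a <- multitaper_cross_spectra(ts, compute_coherence = FALSE)
  b <- multitaper_cross_spectra(ts, weights = rep(1, 3000),
                                compute_coherence = FALSE)
  expect_equal(a$psd, b$psd, tolerance = 1e-12)
})

test_that("identical parcels are perfectly coherent", {
  set.seed(6)
  x <- rnorm(5000)
  mt <- multitaper_cross_spectra(parcel_ts(cbind(x, x), 250))
  expect_true(all(abs(mt$coherence - 1) < 1e-8))
})

test_that("one-hot weighting equals the segment-wise multitaper oracle", {
  set.seed(7)
  fs <- 250; wl <- 2 * fs
  # alternate 10 Hz / 30 Hz content in 2-s blocks aligned to windows
  n_win <- 12
  win_state <- rep(1:2, length.out = n_win)
  state <- rep(win_state, each = wl)
  x <- rnorm(length(state), sd = 0.1)
  x[state == 1] <- x[state == 1] + sin(2 * pi * 10 * which(state == 1) / fs)
  x[state == 2] <- x[state == 2] + sin(2 * pi * 30 * which(state == 2) / fs)
  ts <- parcel_ts(cbind(x, rnorm(length(x))), fs)
  for (k in 1:2) {
    w <- as.numeric(state == k)
    est <- multitaper_cross_spectra(ts, w, compute_coherence = FALSE)
    orc <- oracle_segment_psd(ts$data[, 1], fs, wl, which(win_state == k))
    sel <- orc$freq >= 1 & orc$freq <= 45
    expect_lt(max(abs(est$psd[, 1] - orc$psd[sel]) /
                    pmax(abs(orc$psd[sel]), 1e-12)), 1e-6)
  }
})

test_that("coherence is invariant under per-parcel rescaling", {
  set.seed(8)
  x <- matrix(rnorm(4000), 2000, 2)
  x[, 2] <- 0.5 * x[, 1] + 0.5 * x[, 2]
  a <- multitaper_cross_spectra(parcel_ts(x, 250))$coherence
  b <- multitaper_cross_spectra(parcel_ts(x %*% diag(c(7, 0.1)), 250))$coherence
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("Welch and multitaper agree on the peak bin of a tone", {
  ts <- sine_ts(20, fs = 250, dur = 20)
  pw <- welch_psd(ts)
  mt <- multitaper_cross_spectra(ts, compute_coherence = FALSE)
  expect_equal(pw$freq[which.max(pw$power[, 1])],
               mt$freq[which.max(mt$psd[, 1])])
})

test_that("coherence network thresholding keeps the top percentile", {
  # synthetic spectra object with known band-averaged coherence
  P <- 15  # 105 edges
  set.seed(9)
  vals <- matrix(0, P, P)
  vals[upper.tri(vals)] <- seq(0.001, 0.9, length.out = 105)
  vals <- vals + t(vals); diag(vals) <- 1
  fake <- list(freq = c(5, 10), coherence = array(rep(vals, each = 2),
                                                  dim = c(2, P, P)))
  adj <- coherence_network(fake, band = c(2, 20), percentile = 97)
  expect_equal(sum(adj[upper.tri(adj)] > 0), ceiling(0.03 * 105) - 0)
  # degenerate: all edges equal -> everything at the threshold survives
  same <- array(0.5, dim = c(2, P, P))
  fake2 <- list(freq = c(5, 10), coherence = same)
  adj2 <- coherence_network(fake2, band = c(2, 20))
  expect_true(all(adj2[upper.tri(adj2)] == 0.5))
})

test_that("weighted cross-spectral diagonals match the weighted psd", {
  set.seed(10)
  ts <- parcel_ts(matrix(rnorm(6000), 3000, 2), 250)
  w <- runif(3000)
  mt <- multitaper_cross_spectra(ts, w)
  expect_equal(Re(mt$csd[, 1, 1]), mt$psd[, 1], tolerance = 1e-10)
  # Hermitian symmetry
  expect_equal(mt$csd[, 1, 2], Conj(mt$csd[, 2, 1]), tolerance = 1e-12)
})
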