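test_that("Hilbert envelope recovers amplitude and modulation", {
  fs <- 250
  t0 <- seq_len(20 * fs) / fs
  env <- hilbert_envelope(2 * sin(2 * pi * 20 * t0))
  mid <- env[500:4500]
  expect_true(all(abs(mid - 2) < 0.04))          # within 2% of A = 2
  expect_true(all(hilbert_envelope(rep(0, 100)) == 0))
  # 1 Hz amplitude modulation is demodulated
  mod <- 1 + 0.5 * sin(2 * pi * 1 * t0)
  env2 <- hilbert_envelope(mod * sin(2 * pi * 20 * t0))
  sel <- 500:4500
  expect_gt(cor(env2[sel], mod[sel]), 0.99)
  expect_true(all(env2 >= 0))
})

test_that("duration rule keeps 20-sample runs and drops 10-sample runs", {
  fs <- 250
  cfg <- burst_config(band = c(18, 25))
  base <- rep(c(0.05, 0.1), length.out = 5000)   # 75th percentile = 0.1
  for (len in c(20L, 14L, 13L, 10L)) {
    env <- base
    env[1000:(1000 + len - 1L)] <- 5
    tr <- detect_bursts(env, fs, cfg)
    expected <- if (len >= 14L) 1L else 0L       # > one 18 Hz cycle (55.6 ms)
    expect_equal(track_metrics(tr)$n_events, expected)
  }
  expect_equal(attr(detect_bursts(base, fs, cfg), "min_samples"), 14L)
})

test_that("a constant envelope yields no bursts", {
  tr <- detect_bursts(rep(1, 1000), 250, burst_config())
  expect_equal(sum(tr$on), 0)
})

test_that("burst detection is invariant to monotone envelope transforms", {
  set.seed(12)
  env <- abs(rnorm(5000)) + 0.1
  cfg <- burst_config()
  a <- detect_bursts(env, 250, cfg)
  b <- detect_bursts(env^3, 250, cfg)
  expect_equal(a$on, b$on)
})

test_that("raising the threshold percentile never raises burst FO", {
  set.seed(13)
  env <- hilbert_envelope(burstnet:::fir_bandpass(rnorm(10000), 250, 18, 25,
                                                  trans_bw = 3))
  fos <- vapply(c(60, 75, 90), function(p)
    mean(detect_bursts(env, 250,
                       burst_config(threshold_percentile = p))$on),
    numeric(1))
  expect_true(all(diff(fos) <= 0))
})

test_that("masked samples cannot carry bursts", {
  env <- abs(rnorm(2000)) + 0.1
  env[500:700] <- 10
  mask <- rep(TRUE, 2000); mask[550:620] <- FALSE
  tr <- detect_bursts(env, 250, burst_config(), mask)
  expect_true(all(!tr$on[550:620]))
  expect_error(detect_bursts(env, 250, burst_config(),
                             rep(FALSE, 2000)), "masked")
})

test_that("planted envelope events are recovered with high precision", {
  set.seed(14)
  fs <- 250
  n <- 20000
  on_true <- rep(FALSE, n)
  starts <- seq(500, n - 500, by = 200)
  for (s in starts) on_true[s:(s + 59)] <- TRUE   # 240 ms events
  carrier <- sin(2 * pi * 20 * seq_len(n) / fs)
  x <- carrier * ifelse(on_true, 3, 0.3) + rnorm(n, sd = 0.1)
  env <- hilbert_envelope(burstnet:::fir_bandpass(x, fs, 18, 25, trans_bw = 3))
  tr <- detect_bursts(env, fs, burst_config())
  ev <- burstnet:::track_events(tr$on)
  tru <- burstnet:::track_events(on_true)
  # recall: every planted event intersected by a detected one
  hit <- vapply(seq_len(nrow(tru)), function(i)
    any(ev$onset <= tru$offset[i] & ev$offset >= tru$onset[i]), logical(1))
  expect_gte(mean(hit), 0.9)
  # precision: every detected event intersects a planted one
  ok <- vapply(seq_len(nrow(ev)), function(i)
    any(tru$onset <= ev$offset[i] & tru$offset >= ev$onset[i]), logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("burst beta power is antisymmetric and sign-correct", {
  set.seed(15)
  fs <- 250
  n <- 10000
  on <- rep_len(rep(c(TRUE, FALSE), each = 500), n)
  carrier <- sin(2 * pi * 20 * seq_len(n) / fs)
  x <- carrier * ifelse(on, 2, 1) + rnorm(n, sd = 0.5)
  ts <- parcel_ts(cbind(x, x + rnorm(n, sd = 0.5)), fs)
  tr <- binary_track(on, fs)
  ch <- burst_beta_power(ts, tr, 1:2, band = c(16, 25.5))
  expect_gt(ch, 0)
  tr_flip <- binary_track(!on, fs)
  ch_flip <- burst_beta_power(ts, tr_flip, 1:2, band = c(16, 25.5))
  expect_equal(ch, -ch_flip, tolerance = 1e-10)
  expect_error(burst_beta_power(ts, binary_track(rep(TRUE, n), fs), 1:2),
               "degenerate")
})

test_that("burst beta change is ~0 when statistics match on and off", {
  set.seed(16)
  fs <- 250
  x <- rnorm(20000)
  ts <- parcel_ts(cbind(x, rnorm(20000)), fs)
  on <- rep_len(rep(c(TRUE, FALSE), each = 500), 20000)
  ch <- burst_beta_power(ts, binary_track(on, fs), 1:2)
  expect_lt(abs(ch), 0.005)
})

test_that("full motor burst analysis returns aligned bilateral tracks", {
  set.seed(17)
  co <- distinct_state_cohort(n_sub = 2, dur = 20)
  ts <- zscore_parcels(co$subjects[[1]]$ts)
  mb <- detect_motor_bursts(ts, burst_config(motor_parcels = c(1L, 2L)))
  expect_length(mb$tracks, 2)
  expect_equal(length(mb$combined$on), nrow(ts$data))
  expect_true(all(mb$combined$on == (mb$tracks[[1]]$on | mb$tracks[[2]]$on)))
  expect_true(is.finite(mb$overlap))
})
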