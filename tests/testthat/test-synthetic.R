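test_that("transition-matrix construction and validation behave", {
  P <- make_transition_matrix(4, mean_lifetime = 0.06, fs = 250)
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  expect_equal(unname(diag(P)), rep(1 - 1 / 15, 4))
  expect_equal(stationary_distribution(P), rep(0.25, 4), tolerance = 1e-12)
  bad <- P; bad[2, 1] <- bad[2, 1] + 0.1
  expect_error(sample_state_sequence(bad, NULL, 10), "row\\(s\\) 2")
})

test_that("entry-weight scaling plants the requested FO change exactly", {
  # closed form: f = 0.8 with K = 8 gives entry scale 0.75 and FO 0.10
  r <- burstnet:::entry_scale_for_fo(8, 0.8)
  expect_equal(r, 0.75)
  Ppd <- make_transition_matrix(8, 0.06, 250, c(r, rep(1, 7)))
  expect_equal(stationary_distribution(Ppd)[1], 0.8 / 8, tolerance = 1e-10)
  # numeric solver agrees for non-uniform base weights
  s <- burstnet:::entry_scale_for_fo_general(4, 0.8, 0.06, 250, rep(1, 4))
  Ppd2 <- make_transition_matrix(4, 0.06, 250, c(s, 1, 1, 1))
  expect_equal(stationary_distribution(Ppd2)[1], 0.8 * 0.25,
               tolerance = 1e-8)
})

test_that("an absorbing chain stays in its initial state", {
  s <- sample_state_sequence(diag(2), initial_dist = c(1, 0), 500, seed = 1)
  expect_true(all(s == 1))
})

test_that("sampled chains match stationary occupancy and dwell times", {
  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  s <- sample_state_sequence(P, NULL, 100000, seed = 99)
  expect_lt(abs(mean(s == 1) - 0.5), 0.02)
  # geometric dwell: 1/((1-p) fs) = 40 ms at fs = 250
  m <- track_metrics(s == 1, fs = 250)
  expect_lt(abs(m$mean_lifetime - 0.040) / 0.040, 0.10)
})

test_that("rendered signals carry the planted oscillation", {
  sig <- state_signature(20, 4, c(1, 0, 0), amplitude = 1)
  ts <- render_signals(rep(1L, 5000), list(sig), fs = 250, noise_sd = 0,
                       seed = 5)
  ps <- welch_psd(ts, window_len = 500, overlap = 250)
  expect_equal(ps$freq[which.max(ps$power[, 1])], 20, tolerance = 0.51)
  expect_lt(max(ps$power[, 2]), 1e-20)           # unweighted parcels silent
  # zero-amplitude signatures give pure noise
  ts0 <- render_signals(rep(1L, 5000),
                        list(state_signature(20, 4, c(1, 0, 0),
                                             amplitude = 0)),
                        fs = 250, noise_sd = 1, seed = 5)
  ps0 <- welch_psd(zscore_parcels(ts0))
  expect_lt(max(ps0$power) / mean(ps0$power), 6)  # roughly flat
})

test_that("band power is elevated during the matching state's samples", {
  set.seed(6)
  sigs <- list(state_signature(10, 3, c(1, 0), amplitude = 2),
               state_signature(25, 3, c(1, 0), amplitude = 2))
  states <- rep(rep(1:2, 10), each = 500)
  ts <- render_signals(states, sigs, fs = 250, noise_sd = 1)
  x <- ts$data[, 1]
  bp <- function(idx, lo, hi) {
    y <- burstnet:::fir_bandpass(x, 250, lo, hi, trans_bw = 2)
    mean(y[idx]^2)
  }
  expect_gt(bp(states == 1, 8, 12), bp(states == 2, 8, 12))
  expect_gt(bp(states == 2, 23, 27), bp(states == 1, 23, 27))
})

test_that("cohorts are reproducible and carry exact planted metrics", {
  spec <- cohort_spec(n_hc = 2, n_pd = 2, n_parcels = 4, duration = 10,
                      n_states = 3, seed = 42)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$subjects[[3]]$ts$data, b$subjects[[3]]$ts$data)
  expect_identical(a$covariates, b$covariates)
  # planted metrics recompute exactly from the stored sequence
  for (i in seq_along(a$subjects)) {
    st <- a$subjects[[i]]$states
    for (k in 1:3) {
      m <- track_metrics(st == k, fs = 250)
      stored <- a$ground_truth$metrics[[i]]
      expect_identical(m$fo, stored$fo[k])
      expect_identical(m$rate, stored$rate[k])
    }
    expect_equal(sum(a$ground_truth$fo[i, ]), 1, tolerance = 1e-12)
  }
  # symptom scores only for patients
  expect_true(all(is.na(a$covariates$bradykinesia_rigidity[
    a$covariates$group == "HC"])))
  expect_true(all(!is.na(a$covariates$bradykinesia_rigidity[
    a$covariates$group == "PD"])))
})

test_that("equal group matrices plant no FO effect; scaled entries do", {
  null_spec <- cohort_spec(n_hc = 12, n_pd = 12, n_parcels = 3,
                           duration = 40, n_states = 3, pd_fo_scale = 1,
                           seed = 7)
  co <- generate_cohort(null_spec)
  grp <- co$ground_truth$groups
  tt <- t.test(co$ground_truth$fo[grp == "HC", 1],
               co$ground_truth$fo[grp == "PD", 1])
  expect_gt(tt$p.value, 0.05)
  eff_spec <- cohort_spec(n_hc = 32, n_pd = 32, n_parcels = 3,
                          duration = 40, n_states = 3, pd_fo_scale = 0.8,
                          seed = 8)
  co2 <- generate_cohort(eff_spec)
  grp2 <- co2$ground_truth$groups
  tt2 <- t.test(co2$ground_truth$fo[grp2 == "HC", 1],
                co2$ground_truth$fo[grp2 == "PD", 1])
  expect_lt(tt2$p.value, 0.05)
  expect_gt(tt2$estimate[1], tt2$estimate[2])
})
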