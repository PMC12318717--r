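make_cov <- function(n = 64, n_pd = 28, seed = 50) {
  set.seed(seed)
  data.frame(group = c(rep("HC", n - n_pd), rep("PD", n_pd)),
             dataset = sample(0:1, n, TRUE),
             age = rnorm(n, 68, 6), sex = sample(0:1, n, TRUE),
             education = rnorm(n, 15, 3),
             handedness = sample(0:1, n, TRUE, prob = c(0.1, 0.9)))
}

test_that("design matrix carries the documented degrees of freedom", {
  dm <- build_design(make_cov())
  expect_equal(ncol(dm$X), 7)
  expect_equal(dm$dof, 57)                       # 64 subjects, 7 regressors
  single <- make_cov(); single$group <- "HC"
  expect_error(build_design(single), "one group")
  dup <- make_cov(); dup$age2 <- dup$age
  expect_error(build_design(dup, c("age", "age2")), "collinear")
})

test_that("GLM t behaves on degenerate and planted endpoints", {
  dm <- build_design(make_cov())
  expect_equal(glm_t(dm, rep(3.5, 64))$t, 0)
  sep <- glm_t(dm, as.numeric(dm$X[, "pd"]))
  expect_true(sep$capped)
  # OLS recovery: planted group effect within 2 SE
  set.seed(51)
  eff <- -1.5
  y <- eff * dm$X[, "pd"] + 0.05 * dm$X[, "age"] + rnorm(64)
  r <- glm_t(dm, y)
  expect_lt(abs(r$estimate - eff), 2 * r$se)
  # NA endpoints: listwise drop
  y[3] <- NA
  r2 <- glm_t(dm, y)
  expect_equal(r2$n_dropped, 1)
  expect_equal(r2$dof, 56)
})

test_that("with no confounds the GLM t equals the two-sample pooled t", {
  cov <- make_cov(n = 30, n_pd = 14, seed = 52)
  dm <- build_design(cov, confounds = character(0))
  set.seed(52)
  y <- rnorm(30) + (cov$group == "PD") * 0.8
  tt <- t.test(y[cov$group == "PD"], y[cov$group == "HC"],
               var.equal = TRUE)
  expect_equal(glm_t(dm, y)$t, unname(tt$statistic), tolerance = 1e-10)
})

test_that("GLM t is invariant to affine rescaling of confounds", {
  cov <- make_cov()
  dm1 <- build_design(cov)
  cov2 <- cov
  cov2$age <- (cov2$age - 50) / 10
  cov2$education <- cov2$education * 3 + 1
  dm2 <- build_design(cov2)
  set.seed(53)
  y <- rnorm(64) + (cov$group == "PD")
  expect_equal(glm_t(dm1, y)$t, glm_t(dm2, y)$t, tolerance = 1e-9)
})

test_that("max-t permutation identifies a planted endpoint", {
  cov <- make_cov(seed = 54)
  dm <- build_design(cov)
  set.seed(54)
  Y <- matrix(rnorm(64 * 4), 64, 4)
  Y[, 2] <- Y[, 2] + 5 * (cov$group == "PD")
  pr <- maxt_permutation(dm, Y, n_perm = 500, seed = 3)
  expect_equal(pr$p[2], 1 / 501)                 # minimal attainable p
  expect_true(all(pr$p[-2] > 0.05))
  expect_equal(length(pr$null), 500)
  expect_true(all(pr$p >= 1 / 501 & pr$p <= 1))
  # identity shuffle reproduces observed t
  Xp <- burstnet:::shuffle_design(dm, seq_len(64))
  expect_equal(burstnet:::ols_contrast_t(Xp, dm$contrast, Y)$t, pr$t)
})

test_that("cluster permutation finds a planted band and nothing else", {
  cov <- make_cov(seed = 55)
  dm <- build_design(cov)
  freq <- seq(1, 45, 0.5)
  set.seed(55)
  S <- matrix(rnorm(64 * length(freq)), 64)
  none <- cluster_permutation_spectra(dm, S, freq, n_perm = 200, seed = 1)
  if (!is.null(none$clusters)) expect_true(all(none$clusters$p > 0.05))
  band <- freq >= 16 & freq <= 25.5
  S2 <- S
  S2[cov$group == "PD", band] <- S2[cov$group == "PD", band] - 1.2
  found <- cluster_permutation_spectra(dm, S2, freq, n_perm = 200, seed = 1)
  expect_false(is.null(found$clusters))
  top <- found$clusters[which.min(found$clusters$p), ]
  expect_lt(top$p, 0.05)
  expect_lte(top$freq_lo, 17)
  expect_gte(top$freq_hi, 24)
  expect_lt(top$sum_t, 0)                        # PD decrease
  # identical spectra -> no clusters
  S3 <- matrix(1, 64, length(freq)) + rnorm(64 * length(freq), sd = 1e-9)
  id <- cluster_permutation_spectra(dm, S3, freq, n_perm = 50, seed = 1)
  expect_true(is.null(id$clusters) || all(abs(id$clusters$sum_t) < 1e3))
})

test_that("FO-spectrum projection recovers noiseless slopes", {
  set.seed(56)
  n <- 40
  fo <- runif(n, 0.05, 0.25)
  freq <- seq(1, 45, 1)
  b <- sin(freq / 5)
  spectra <- outer(rep(1, n), freq * 0) + 2 + fo %o% b
  pr <- fo_spectrum_projection(fo, spectra, freq = freq)
  expect_equal(unname(pr$slopes), b, tolerance = 1e-10)
  # projections evaluate the fitted line at the grid
  expect_equal(pr$projection[, 1], 2 + pr$fo_grid[1] * b, tolerance = 1e-9)
  # independence -> slopes near zero
  pr0 <- fo_spectrum_projection(runif(n), matrix(rnorm(n * 45), n),
                                freq = freq)
  expect_lt(max(abs(pr0$slope_t)), 5)
  expect_error(fo_spectrum_projection(rep(0.1, n), spectra), "constant")
})

test_that("symptom GLM flags a planted association only", {
  set.seed(57)
  n <- 28
  sc <- cbind(bradykinesia_rigidity = rnorm(n, 15, 6),
              tremor = rnorm(n, 5, 3))
  y <- 0.2 * sc[, 1] + rnorm(n, sd = 0.5)
  pr <- symptom_glm(y, sc, n_perm = 400, seed = 2)
  expect_lt(pr$p[1], 0.05)
  expect_gt(pr$t[1], 0)
  y0 <- rnorm(n)
  pr0 <- symptom_glm(y0, sc, n_perm = 400, seed = 2)
  expect_true(all(pr0$p >= 1 / 401))
  expect_error(symptom_glm(y, cbind(a = rep(NA_real_, n),
                                    b = rep(NA_real_, n))), "missing")
})

test_that("pearson correlation matches closed-form cases", {
  x <- rnorm(30)
  expect_equal(pearson_r(x, 2 * x)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_error(pearson_r(x, rep(1, 30)), "constant")
  set.seed(58)
  rs <- replicate(300, pearson_r(rnorm(64), rnorm(64))$r)
  expect_lt(abs(mean(rs)), 0.02)
  expect_lt(abs(sd(rs) - 1 / sqrt(63)), 0.02)
})
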