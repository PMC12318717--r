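# -- confound-adjusted GLM contrasts and permutation inference ---------

#' Build a group-contrast design matrix
#'
#' Two group-indicator columns (HC, PD; no intercept) plus confound
#' regressors. Sign convention: the contrast is PD minus HC, so an
#' endpoint that is reduced in the patient group yields a negative t.
#'
#' @param covariates data frame with a `group` column (values `"HC"` /
#'   `"PD"`) and the confound columns.
#' @param confounds character vector of confound column names.
#' @return A `design_matrix`: `X`, `contrast`, `dof`, column `names`.
#' @export
build_design <- function(covariates,
                         confounds = c("dataset", "age", "sex",
                                       "education", "handedness")) {
  g <- covariates$group
  if (length(unique(g)) < 2L)
    stop("contrast undefined: only one group present")
  miss <- confounds[!confounds %in% names(covariates)]
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  X <- cbind(hc = as.numeric(g == "HC"), pd = as.numeric(g == "PD"))
  for (cc in confounds) {
    v <- covariates[[cc]]
    if (anyNA(v)) stop("missing values in confound '", cc, "'")
    X <- cbind(X, as.numeric(v))
  }
  colnames(X) <- c("hc", "pd", confounds)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  ctr <- c(-1, 1, rep(0, length(confounds)))
  names(ctr) <- colnames(X)
  structure(list(X = X, contrast = ctr,
                 dof = nrow(X) - ncol(X), names = colnames(X),
                 group_cols = 1:2),
            class = "design_matrix")
}

# core OLS contrast t for one design and response matrix Y (n x m);
# assumes complete Y. Returns list(t, est, se, dof).
ols_contrast_t <- function(X, ctr, Y) {
  n <- nrow(X); p <- ncol(X)
  XtX <- crossprod(X)
  XtXi <- chol2inv(chol(XtX))
  B <- XtXi %*% crossprod(X, Y)            # p x m
  res <- Y - X %*% B
  dof <- n - p
  sigma2 <- colSums(res^2) / dof
  cvar <- drop(t(ctr) %*% XtXi %*% ctr)
  est <- drop(crossprod(ctr, B))
  se <- sqrt(cvar * sigma2)
  # exact fits (zero residual variance up to round-off) have no valid
  # t; report 0 for a zero contrast, a capped value otherwise
  scale2 <- colMeans(Y^2) + .Machine$double.xmin
  degen <- sigma2 < 1e-20 * scale2
  zero_est <- abs(est) < 1e-8 * sqrt(scale2)
  t <- ifelse(degen, ifelse(zero_est, 0, sign(est) * 1e6), est / se)
  list(t = t, est = est, se = se, dof = dof,
       capped = degen & !zero_est)
}

#' GLM contrast t-statistic for one endpoint
#'
#' Ordinary least squares fit of the endpoint on the design; subjects
#' with undefined endpoint values are dropped listwise (count
#' reported). Degenerate fits with zero residual variance are capped
#' and flagged.
#'
#' @param dm a [build_design()] result.
#' @param y per-subject endpoint values (may contain `NA`).
#' @return List with `t`, `estimate`, `se`, `dof`, `n_dropped`,
#'   `capped`.
#' @export
glm_t <- function(dm, y) {
  keep <- is.finite(y)
  X <- dm$X[keep, , drop = FALSE]
  if (nrow(X) <= ncol(X)) stop("too few defined endpoints for the design")
  r <- ols_contrast_t(X, dm$contrast, cbind(y[keep]))
  list(t = unname(r$t), estimate = unname(r$est), se = unname(r$se),
       dof = r$dof, n_dropped = sum(!keep), capped = unname(r$capped))
}

shuffle_design <- function(dm, perm) {
  X <- dm$X
  X[, dm$group_cols] <- X[perm, dm$group_cols, drop = FALSE]
  X
}

#' Maximum-t-statistic permutation test across endpoints
#'
#' Shuffles group labels (confounds fixed), recomputes the GLM contrast
#' t for every endpoint, and keeps the largest |t| per permutation as
#' the single null distribution controlling the family-wise error over
#' endpoints. `p = (1 + #\{null >= |t_obs|\}) / (n_perm + 1)`.
#'
#' @param dm a [build_design()] result.
#' @param endpoints numeric matrix, subjects x endpoints (a single
#'   endpoint degenerates to an ordinary permutation test). `NA`s are
#'   handled per endpoint by listwise deletion.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return A `permutation_result`: observed `t` per endpoint, `null`
#'   max-|t| distribution, `p`, `threshold` (95th percentile of the
#'   null), `dof`, `n_perm`, `seed`.
#' @export
maxt_permutation <- function(dm, endpoints, n_perm = 10000, seed = 1L) {
  endpoints <- as.matrix(endpoints)
  m <- ncol(endpoints)
  set.seed(seed)
  complete <- !anyNA(endpoints)
  obs <- if (complete)
    ols_contrast_t(dm$X, dm$contrast, endpoints)$t
  else
    vapply(seq_len(m), function(j) glm_t(dm, endpoints[, j])$t, numeric(1))
  null <- numeric(n_perm)
  n <- nrow(dm$X)
  for (b in seq_len(n_perm)) {
    Xp <- shuffle_design(dm, sample.int(n))
    tb <- if (complete)
      ols_contrast_t(Xp, dm$contrast, endpoints)$t
    else
      vapply(seq_len(m), function(j) {
        keep <- is.finite(endpoints[, j])
        ols_contrast_t(Xp[keep, , drop = FALSE], dm$contrast,
                       cbind(endpoints[keep, j]))$t
      }, numeric(1))
    null[b] <- max(abs(tb))
  }
  p <- vapply(obs, function(t0) (1 + sum(null >= abs(t0))) / (n_perm + 1),
              numeric(1))
  structure(list(t = obs, null = null, p = p,
                 threshold = quantile(null, 0.95, names = FALSE),
                 dof = dm$dof, n_perm = n_perm, seed = seed,
                 endpoints = colnames(endpoints)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %d endpoint(s), %d permutations\n",
              length(x$t), x$n_perm))
  df <- data.frame(endpoint = x$endpoints %||% seq_along(x$t),
                   t = round(x$t, 3), p = signif(x$p, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cluster-based permutation contrast of spectra
#'
#' Per-frequency GLM contrast t; contiguous bins whose |t| exceeds the
#' cluster-forming threshold (t quantile at `cluster_alpha`, two-sided)
#' form clusters of a common sign; the cluster statistic is the summed
#' t (the mean t is reported as well); the null is the maximal absolute
#' cluster sum under group-label permutation.
#'
#' @param dm a [build_design()] result.
#' @param spectra subjects x frequencies matrix of power values.
#' @param freq frequency grid (Hz) for reporting.
#' @param n_perm number of permutations.
#' @param cluster_alpha per-bin two-sided alpha forming clusters.
#' @param seed RNG seed.
#' @return List with per-bin `t`, `clusters` (data frame: bin range,
#'   frequency range, sum and mean t, p), the `null` distribution and
#'   the forming `threshold`.
#' @export
cluster_permutation_spectra <- function(dm, spectra, freq = NULL,
                                        n_perm = 1000,
                                        cluster_alpha = 0.05, seed = 1L) {
  spectra <- as.matrix(spectra)
  nf <- ncol(spectra)
  if (is.null(freq)) freq <- seq_len(nf)
  set.seed(seed)
  thr <- qt(1 - cluster_alpha / 2, dm$dof)
  tobs <- ols_contrast_t(dm$X, dm$contrast, spectra)$t

  find_clusters <- function(tv) {
    supra <- abs(tv) > thr
    if (!any(supra)) return(NULL)
    sgn <- sign(tv)
    id <- cumsum(c(TRUE, diff(supra) != 0 | diff(sgn) != 0))
    keep <- split(seq_len(nf), id)
    keep <- keep[vapply(keep, function(ix) all(supra[ix]), logical(1))]
    keep
  }
  cl <- find_clusters(tobs)
  null <- numeric(n_perm)
  n <- nrow(dm$X)
  for (b in seq_len(n_perm)) {
    tb <- ols_contrast_t(shuffle_design(dm, sample.int(n)),
                         dm$contrast, spectra)$t
    cb <- find_clusters(tb)
    null[b] <- if (is.null(cb)) 0 else
      max(vapply(cb, function(ix) abs(sum(tb[ix])), numeric(1)))
  }
  clusters <- NULL
  if (!is.null(cl)) {
    clusters <- do.call(rbind, lapply(cl, function(ix) {
      s <- sum(tobs[ix])
      data.frame(bin_lo = min(ix), bin_hi = max(ix),
                 freq_lo = freq[min(ix)], freq_hi = freq[max(ix)],
                 sum_t = s, mean_t = mean(tobs[ix]),
                 peak_freq = freq[ix[which.max(abs(tobs[ix]))]],
                 p = (1 + sum(null >= abs(s))) / (n_perm + 1))
    }))
    rownames(clusters) <- NULL
  }
  list(t = tobs, freq = freq, clusters = clusters, null = null,
       threshold = thr, dof = dm$dof, n_perm = n_perm)
}

#' Per-frequency regression of power on fractional occupancy
#'
#' Fits one GLM per frequency predicting subjects' spectral power from
#' a state's FO (plus confounds) and returns the fitted projection at
#' chosen FO values with confounds held at their means.
#'
#' @param fo per-subject FO values.
#' @param spectra subjects x frequencies power matrix.
#' @param confounds optional subjects x q matrix/data frame.
#' @param fo_grid FO values at which to project (default quartiles).
#' @param freq frequency grid for reporting.
#' @return List with `freq`, `slopes`, `slope_t`, `fo_grid`, and
#'   `projection` (frequencies x length(fo_grid)).
#' @export
fo_spectrum_projection <- function(fo, spectra, confounds = NULL,
                                   fo_grid = NULL, freq = NULL) {
  if (sd(fo) == 0) stop("FO is constant across subjects")
  spectra <- as.matrix(spectra)
  n <- nrow(spectra)
  if (is.null(fo_grid))
    fo_grid <- quantile(fo, c(0.1, 0.5, 0.9), names = FALSE)
  if (is.null(freq)) freq <- seq_len(ncol(spectra))
  X <- cbind(intercept = 1, fo = fo)
  if (!is.null(confounds)) X <- cbind(X, as.matrix(confounds))
  XtXi <- chol2inv(chol(crossprod(X)))
  B <- XtXi %*% crossprod(X, spectra)      # p x F
  res <- spectra - X %*% B
  dof <- n - ncol(X)
  sigma2 <- colSums(res^2) / dof
  se <- sqrt(XtXi[2, 2] * sigma2)
  slopes <- B[2, ]
  xbar <- colMeans(X)
  proj <- vapply(fo_grid, function(f0) {
    xv <- xbar; xv[2] <- f0
    drop(t(B) %*% xv)
  }, numeric(ncol(spectra)))
  list(freq = freq, slopes = slopes,
       slope_t = ifelse(se > 0, slopes / se, 0),
       fo_grid = fo_grid, projection = proj, dof = dof)
}

#' Symptom-association GLM with max-t permutation
#'
#' Predicts a metric from Bradykinesia/Rigidity and Tremor scores in
#' the patient group, controlling for confounds; significance of the
#' two score regressors is assessed jointly with a max-|t| permutation
#' test that shuffles the score rows.
#'
#' @param y per-patient metric values.
#' @param scores data frame/matrix with columns
#'   `bradykinesia_rigidity` and `tremor`.
#' @param confounds optional matrix/data frame of confounds.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return A `permutation_result` with one t/p per score.
#' @export
symptom_glm <- function(y, scores, confounds = NULL, n_perm = 10000,
                        seed = 1L) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stop("expected two score columns")
  if (all(is.na(scores))) stop("all symptom scores missing")
  keep <- is.finite(y) & stats::complete.cases(scores)
  y <- y[keep]; S <- scores[keep, , drop = FALSE]
  C <- if (is.null(confounds)) NULL else as.matrix(confounds)[keep, , drop = FALSE]
  n <- length(y)
  set.seed(seed)
  tfun <- function(Sp) {
    X <- cbind(1, Sp, C)
    XtXi <- chol2inv(chol(crossprod(X)))
    B <- XtXi %*% crossprod(X, y)
    res <- y - X %*% B
    dof <- n - ncol(X)
    sigma2 <- sum(res^2) / dof
    se <- sqrt(diag(XtXi)[2:3] * sigma2)
    ifelse(se > 0, B[2:3] / se, 0)
  }
  obs <- tfun(S)
  null <- numeric(n_perm)
  for (b in seq_len(n_perm))
    null[b] <- max(abs(tfun(S[sample.int(n), , drop = FALSE])))
  p <- vapply(obs, function(t0) (1 + sum(null >= abs(t0))) / (n_perm + 1),
              numeric(1))
  structure(list(t = as.numeric(obs), null = null, p = p,
                 threshold = quantile(null, 0.95, names = FALSE),
                 dof = n - 3 - if (is.null(C)) 0 else ncol(C),
                 n_perm = n_perm, seed = seed,
                 endpoints = c("bradykinesia_rigidity", "tremor")),
            class = "permutation_result")
}

#' Pearson correlation with test
#'
#' @param x,y per-subject scalars (n >= 3, non-constant).
#' @return List with `r`, `p`, `n`, `dof`.
#' @export
pearson_r <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       dof = unname(ct$parameter))
}
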