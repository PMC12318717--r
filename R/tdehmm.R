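# -- time-delay-embedded hidden Markov model ---------------------------
# Each hidden state is a zero-mean Gaussian over time-delay-embedded,
# PCA-reduced data, so states capture distinct auto- and
# cross-covariance (i.e. spectral/network) structure. Inference is
# full-batch EM; the model-selection objective reported as free energy
# is the negative log-likelihood (lower is better), which EM decreases
# monotonically.

#' Time-delay embedding
#'
#' Row t of the embedded matrix contains the values of every parcel at
#' lags `-L ... +L` around sample t. The first and last L samples have
#' no complete window and are dropped (posteriors are padded back
#' later).
#'
#' @param x numeric matrix (samples x parcels) or [parcel_ts].
#' @param lags half-width L of the lag window in samples (default 7,
#'   i.e. 15 lags).
#' @return `(T - 2L) x ((2L+1) * P)` matrix; columns are ordered parcel
#'   by parcel, lag -L..L within parcel.
#' @export
tde_embed <- function(x, lags = 7) {
  if (inherits(x, "parcel_ts")) x <- x$data
  if (nrow(x) <= 2 * lags) stop("recording shorter than the embedding window")
  .tde_embed_cpp(x, as.integer(lags))
}

#' PCA reduction of embedded data
#'
#' Columns are standardised (so no lag dominates), then projected onto
#' the leading principal components of the covariance matrix.
#'
#' @param embedded matrix from [tde_embed()] (possibly row-bound across
#'   subjects).
#' @param n_components number of components (convention: 2 x number of
#'   parcels).
#' @return List with `scores`, orthonormal `rotation`, per-component
#'   `eigenvalues`, `explained` variance fractions, and the
#'   standardisation `center`/`scale`.
#' @export
pca_reduce <- function(embedded, n_components) {
  if (n_components > min(dim(embedded)))
    stop("n_components exceeds the rank bound min(rows, columns)")
  ctr <- colMeans(embedded)
  scl <- apply(embedded, 2, sd)
  if (any(scl == 0)) stop("constant embedded column(s); cannot standardise")
  z <- sweep(sweep(embedded, 2, ctr), 2, scl, "/")
  cv <- crossprod(z) / (nrow(z) - 1)
  e <- eigen(cv, symmetric = TRUE)
  rot <- e$vectors[, seq_len(n_components), drop = FALSE]
  list(scores = z %*% rot, rotation = rot,
       eigenvalues = e$values,
       explained = e$values[seq_len(n_components)] / sum(e$values),
       center = ctr, scale = scl)
}

# Streaming equivalent of pca_reduce over a list of embedded matrices:
# pooled column standardisation (so the covariance of the standardised
# data is the pooled correlation matrix) without materialising the
# row-bound standardised copy. scores_i = E_i %*% proj - offset.
pca_stream <- function(emb_list, n_components) {
  d <- ncol(emb_list[[1]])
  if (n_components > d) stop("n_components exceeds the column count")
  n <- sum(vapply(emb_list, nrow, integer(1)))
  cs <- Reduce(`+`, lapply(emb_list, colSums))
  cp <- Reduce(`+`, lapply(emb_list, crossprod))
  ctr <- cs / n
  cv <- (cp - n * tcrossprod(ctr)) / (n - 1)
  scl <- sqrt(diag(cv))
  if (any(scl == 0)) stop("constant embedded column(s); cannot standardise")
  cr <- cv / tcrossprod(scl)
  e <- eigen(cr, symmetric = TRUE)
  rot <- e$vectors[, seq_len(n_components), drop = FALSE]
  proj <- rot / scl              # rows scaled: (E/scl) %*% rot
  list(proj = proj, offset = drop(crossprod(rot, ctr / scl)),
       rotation = rot, eigenvalues = e$values,
       explained = e$values[seq_len(n_components)] / sum(e$values),
       center = ctr, scale = scl)
}

# log multivariate normal density, zero mean, for all rows of X under
# each state covariance; returns T x K matrix (compiled kernel)
gaussian_logdens <- function(X, covs) {
  .gauss_logdens_cpp(X, covs)
}

# EM engine over one concatenated data matrix with subject boundaries;
# returns a function advancing parameters by n_iter iterations
make_em_engine <- function(X, starts, ends, K, tol) {
  Ttot <- nrow(X)
  n_seq <- length(starts)
  function(p, n_iter) {
    covs <- p$covs; A <- p$A; pi0 <- p$pi0
    trace <- p$trace %||% numeric(0)
    prev <- if (length(trace)) trace[length(trace)] else Inf
    converged <- FALSE
    jitter <- p$jitter %||% 0
    for (iter in seq_len(n_iter)) {
      it <- .em_iteration_cpp(X, covs, A, pi0, starts, ends)
      fe <- -it$loglik
      trace <- c(trace, fe)
      if (is.finite(prev) && abs(prev - fe) < tol * abs(prev)) {
        converged <- TRUE
        break
      }
      prev <- fe
      # M-step
      if (K > 1) {
        A <- it$xi / pmax(rowSums(it$xi), .Machine$double.eps)
        A <- A / rowSums(A)
      }
      pi0 <- as.numeric(it$pi_acc) / sum(it$pi_acc)
      for (k in seq_len(K)) {
        S <- ridge_chol_fix(it$scatter[, , k] / it$g_tot[k])
        jitter <- jitter + attr(S, "jitter")
        covs[[k]] <- S
      }
    }
    list(covs = covs, A = A, pi0 = pi0, trace = trace,
         converged = converged, jitter = jitter)
  }
}

ridge_chol_fix <- function(S) {
  jitter <- 0
  base <- mean(diag(S))
  for (expo in c(-8, -6, -4, -2)) {
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (ok) break
    jitter <- base * 10^expo
    S <- S + diag(jitter, nrow(S))
  }
  attr(S, "jitter") <- jitter
  S
}

#' Fit a zero-mean Gaussian HMM by EM (one run)
#'
#' @param data matrix or list of per-subject matrices of reduced
#'   embedded observations (subjects are treated as independent
#'   sequences sharing parameters).
#' @param K number of states.
#' @param seed initialisation seed (random block assignment of samples
#'   to states).
#' @param max_iter maximum EM iterations (including the short-start
#'   phase).
#' @param tol convergence threshold on the relative free-energy change.
#' @param n_starts number of random initialisations evaluated for
#'   `start_iter` iterations before the best one is continued; guards
#'   a run against poor random starts at little extra cost.
#' @param start_iter EM iterations per short start.
#' @return An `hmm_fit`: transition matrix `A`, initial distribution
#'   `pi`, state covariances `covs`, `free_energy` (negative
#'   log-likelihood; lower is better), iteration `trace`, `seed`, `K`,
#'   and a `converged` flag.
#' @export
fit_hmm <- function(data, K, seed = 1L, max_iter = 50L, tol = 1e-6,
                    n_starts = 1L, start_iter = 2L) {
  if (is.matrix(data)) data <- list(data)
  stopifnot(K >= 1, length(data) >= 1)
  all_X <- do.call(rbind, data)
  Ttot <- nrow(all_X)
  # subject boundaries within the concatenated matrix (subjects are
  # independent sequences; the E-step recursion restarts at each)
  lens <- vapply(data, nrow, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L

  # random contiguous-block initialisation of the state covariances
  init_params <- function(sub_seed) {
    set.seed(sub_seed)
    covs <- vector("list", K)
    block <- max(50L, Ttot %/% (K * 20L))
    blk_state <- sample(rep_len(seq_len(K), ceiling(Ttot / block)))
    lab <- rep(blk_state, each = block)[seq_len(Ttot)]
    for (k in seq_len(K)) {
      rows <- which(lab == k)
      covs[[k]] <- ridge_chol_fix(crossprod(all_X[rows, , drop = FALSE]) /
                                    length(rows))
    }
    A <- matrix((1 - 0.9) / max(K - 1, 1), K, K)
    diag(A) <- if (K > 1) 0.9 else 1
    list(covs = covs, A = A, pi0 = rep(1 / K, K))
  }

  em_full <- make_em_engine(all_X, starts, ends, K, tol)

  # short multi-start phase guards one full run against poor random
  # initialisations: each candidate is advanced a few iterations on a
  # deterministic half of the subjects (cheap), the lowest free energy
  # wins, and only the winner is fitted on the full data
  n_starts <- max(1L, as.integer(n_starts))
  short <- max_iter > start_iter && n_starts > 1L && length(data) > 1L
  cand <- lapply(seq_len(n_starts), function(s)
    init_params(seed * 131L %% 2147483647L + s))
  if (short) {
    sub <- seq(1L, length(data), by = 2L)
    sub_X <- do.call(rbind, data[sub])
    sub_lens <- lens[sub]
    sub_ends <- cumsum(sub_lens)
    em_sub <- make_em_engine(sub_X, sub_ends - sub_lens + 1L, sub_ends,
                             K, tol)
    scored <- lapply(cand, em_sub, n_iter = start_iter)
    fe <- vapply(scored, function(p) p$trace[length(p$trace)], numeric(1))
    winner <- scored[[which.min(fe)]]
    winner$trace <- numeric(0)  # subset objective; full trace starts fresh
    run <- em_full(winner, max_iter - start_iter)
  } else {
    run <- em_full(cand[[1]], max_iter)
  }
  structure(list(A = run$A, pi = run$pi0, covs = run$covs,
                 free_energy = run$trace[length(run$trace)],
                 trace = run$trace, seed = seed, K = K,
                 converged = run$converged, jitter = run$jitter),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("<hmm_fit> K = %d, free energy %.2f, %d iterations%s\n",
              x$K, x$free_energy, length(x$trace),
              if (x$converged) " (converged)" else " (max_iter)"))
  invisible(x)
}

#' Select the best of several HMM runs
#'
#' Picks the run with the lowest free energy; exact ties are broken by
#' the lowest seed.
#'
#' @param fits list of `hmm_fit`s with a common K.
#' @return The selected `hmm_fit`.
#' @export
select_best_run <- function(fits) {
  if (length(fits) == 0) stop("no fits supplied")
  Ks <- vapply(fits, `[[`, numeric(1), "K")
  if (length(unique(Ks)) != 1) stop("fits mix different numbers of states")
  fe <- vapply(fits, `[[`, numeric(1), "free_energy")
  seeds <- vapply(fits, `[[`, numeric(1), "seed")
  best <- which(fe == min(fe))
  fits[[best[which.min(seeds[best])]]]
}

#' Posterior state probabilities for one subject
#'
#' Forward-backward posteriors over the valid (embedded) samples,
#' padded by L rows at each end with the subject's mean posterior so
#' the time course realigns with the original recording. Padded rows
#' are flagged and excluded from metrics by default.
#'
#' The hard state path used for occupancy tracks is the Viterbi
#' (maximum a-posteriori sequence) path: because it respects the
#' learned transition structure globally, its visit segmentation is
#' considerably less fragmentation-noisy than the per-sample argmax,
#' which matters for event-count metrics (rates, intervals). The
#' per-sample argmax path is kept alongside (`path_argmax`), and
#' posterior-mass FO is always reported by [state_metrics()].
#'
#' @param fit an `hmm_fit`.
#' @param reduced this subject's reduced embedded data.
#' @param lags embedding half-width used (pad length).
#' @param fs sampling rate (carried for metrics).
#' @param path_method `"viterbi"` (default) or `"argmax"` for the hard
#'   path.
#' @return A `state_probs`: `gamma` (samples x K, rows sum to 1),
#'   `path` (hard labels), `path_argmax`, logical `padded`, `fs`,
#'   `loglik`.
#' @export
state_timecourses <- function(fit, reduced, lags = 7, fs = NULL,
                              path_method = c("viterbi", "argmax")) {
  path_method <- match.arg(path_method)
  logB <- gaussian_logdens(reduced, fit$covs)
  fb <- .forward_backward_cpp(logB, log(fit$A), log(fit$pi))
  g <- fb$gamma
  L <- lags
  pad <- matrix(rep(colMeans(g), each = L), L, fit$K)
  gamma <- rbind(pad, g, pad)
  padded <- c(rep(TRUE, L), rep(FALSE, nrow(g)), rep(TRUE, L))
  argmax <- max.col(gamma, ties.method = "first")
  path <- if (path_method == "viterbi" && fit$K > 1) {
    vp <- viterbi_path(logB, log(fit$A), log(fit$pi))
    c(rep(vp[1], L), vp, rep(vp[length(vp)], L))
  } else argmax
  structure(list(gamma = gamma, path = path, path_argmax = argmax,
                 padded = padded, fs = fs, K = fit$K,
                 loglik = fb$loglik),
            class = "state_probs")
}

# max-probability state sequence (compiled log-space dynamic programme)
viterbi_path <- function(logB, logA, logpi) {
  .viterbi_cpp(logB, logA, logpi)
}

#' Per-state dynamics metrics from posteriors
#'
#' Binarises the hard (argmax) state path into one track per state and
#' runs the shared [track_metrics()] engine. Padded samples are
#' excluded; a soft (posterior-mass) FO is reported alongside.
#'
#' @param sp a `state_probs`.
#' @param mask optional retention mask aligned with the padded length.
#' @param fs sampling rate; defaults to `sp$fs`.
#' @return `data.frame` with one row per state: `state`, `fo`,
#'   `mean_lifetime`, `mean_interval`, `rate`, `n_events`, `fo_soft`.
#' @export
state_metrics <- function(sp, mask = NULL, fs = NULL) {
  if (is.null(fs)) fs <- sp$fs
  if (is.null(fs)) stop("sampling rate unknown; pass fs")
  n <- length(sp$path)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (length(mask) != n) stop("mask length mismatch")
  use <- mask & !sp$padded
  out <- do.call(rbind, lapply(seq_len(sp$K), function(k)
    cbind(state = k, track_metrics(sp$path == k, mask = use, fs = fs))))
  out$fo_soft <- colSums(sp$gamma[use, , drop = FALSE]) / sum(use)
  out
}

#' Fit a TDE-HMM to a cohort of recordings
#'
#' Convenience wrapper: embed each subject, pool for PCA, run EM from
#' several seeds, keep the lowest-free-energy run, and return per-
#' subject padded posteriors.
#'
#' @param ts_list list of [parcel_ts] (one per subject).
#' @param K number of states (default 8).
#' @param lags embedding half-width in samples (default 7).
#' @param n_pca number of principal components (default 2 x parcels).
#' @param n_runs number of EM runs (default 3).
#' @param seeds initialisation seeds (default `seq_len(n_runs)`).
#' @param max_iter,tol EM controls.
#' @return List with the selected `fit`, the full `fits` list and
#'   `runs` table (seed, free energy), `posteriors` (per-subject
#'   `state_probs` under the selected fit), the `reduced` per-subject
#'   data, the `pca` basis, `lags`, `K` and `fs`.
#' @export
tde_hmm <- function(ts_list, K = 8, lags = 7, n_pca = NULL, n_runs = 3,
                    seeds = seq_len(n_runs), max_iter = 50L, tol = 1e-6) {
  if (inherits(ts_list, "parcel_ts")) ts_list <- list(ts_list)
  P <- ncol(ts_list[[1]]$data)
  fs <- ts_list[[1]]$fs
  if (is.null(n_pca)) n_pca <- 2L * P
  emb <- lapply(ts_list, tde_embed, lags = lags)
  pca <- pca_stream(emb, n_pca)
  reduced <- lapply(emb, function(E)
    sweep(E %*% pca$proj, 2, pca$offset))
  fits <- lapply(seeds, function(s)
    fit_hmm(reduced, K, seed = s, max_iter = max_iter, tol = tol))
  best <- select_best_run(fits)
  posteriors <- lapply(reduced, function(r)
    state_timecourses(best, r, lags = lags, fs = fs))
  list(fit = best, fits = fits,
       runs = data.frame(seed = vapply(fits, `[[`, numeric(1), "seed"),
                         free_energy = vapply(fits, `[[`, numeric(1),
                                              "free_energy")),
       posteriors = posteriors, reduced = reduced, pca = pca,
       lags = lags, K = K, fs = fs)
}

#' State-specific spectra for one subject
#'
#' Posterior-weighted multitaper: per-window cross-spectra are computed
#' once and combined with each state's window weights (mean posterior
#' probability inside the window). The beta-power change of state k is
#' its in-band motor-parcel power minus the unweighted mean across
#' states, so changes are centred at zero at every frequency.
#'
#' @param ts the subject's [parcel_ts].
#' @param sp the subject's `state_probs` (padded length must match).
#' @param window,n_tapers,nw,fmin,fmax multitaper settings.
#' @param compute_coherence also accumulate parcel x parcel coherence
#'   per state (costlier; off by default).
#' @return List with `freq`, `psd` (frequency x parcel x state array),
#'   `power_change` (same shape, state minus mean across states), and
#'   optionally `coherence` (frequency x P x P x state).
#' @export
state_spectra <- function(ts, sp, window = 2, n_tapers = 7, nw = 4,
                          fmin = 1, fmax = 45, compute_coherence = FALSE) {
  if (length(sp$path) != n_samples(ts))
    stop("posteriors and recording are misaligned")
  mw <- multitaper_windows(ts, window, n_tapers, nw, fmin, fmax,
                           keep_fft = compute_coherence)
  K <- sp$K
  nf <- length(mw$freq)
  P <- ncol(ts$data)
  psd <- array(NA_real_, dim = c(nf, P, K))
  coh <- if (compute_coherence) array(NA_real_, dim = c(nf, P, P, K)) else NULL
  for (k in seq_len(K)) {
    wts <- window_weights(sp$gamma[, k], mw$starts, mw$wl)
    tot <- sum(wts)
    if (tot <= 1e-10) next  # state never visited: flagged missing
    wn <- wts / tot
    pk <- matrix(0, nf, P)
    for (w in seq_along(wn)) pk <- pk + wn[w] * mw$psd[w, , ]
    psd[, , k] <- pk
    if (compute_coherence) {
      S <- cross_spectral_matrix(mw, wn)
      ck <- array(0, dim = c(nf, P, P))
      for (f in seq_len(nf)) {
        dg <- Re(diag(S[f, , ]))
        ck[f, , ] <- Mod(S[f, , ])^2 / outer(dg, dg)
      }
      coh[, , , k] <- ck
    }
  }
  grand <- apply(psd, c(1, 2), mean)  # unweighted mean across states
  change <- psd - array(grand, dim = dim(psd))
  out <- list(freq = mw$freq, psd = psd, power_change = change,
              labels = ts$labels)
  if (compute_coherence) out$coherence <- coh
  out
}

#' Motor-parcel beta-power change per state
#'
#' @param ss output of [state_spectra()].
#' @param motor_parcels parcel indices.
#' @param band Hz interval (default 16-25.5).
#' @return Length-K vector of band-averaged power changes.
#' @export
state_beta_power_change <- function(ss, motor_parcels, band = c(16, 25.5)) {
  sel <- band_bins(ss$freq, band)
  apply(ss$power_change[sel, motor_parcels, , drop = FALSE], 3,
        mean)
}

#' Match state labels between two fits
#'
#' Greedy assignment maximising the correlation between posterior time
#' courses (concatenated across subjects). Used to compare runs, K
#' grids, or a fit against planted ground truth.
#'
#' @param gamma_ref,gamma_new matrices (samples x K) of posteriors on
#'   the same samples.
#' @return Integer vector `m` such that column `m[k]` of `gamma_new`
#'   corresponds to column `k` of `gamma_ref`.
#' @export
match_states <- function(gamma_ref, gamma_new) {
  K <- ncol(gamma_ref)
  C <- suppressWarnings(cor(gamma_ref, gamma_new))
  C[is.na(C)] <- -Inf
  m <- integer(K)
  used <- logical(ncol(gamma_new))
  for (i in order(apply(C, 1, max), decreasing = TRUE)) {
    j <- order(C[i, ], decreasing = TRUE)
    j <- j[!used[j]][1]
    m[i] <- j
    used[j] <- TRUE
  }
  m
}
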