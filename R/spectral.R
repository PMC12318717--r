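# -- spectral estimation -----------------------------------------------
# Welch static spectra, Slepian multitaper cross-spectra with per-sample
# weighting (used for posterior-weighted state spectra and burst-locked
# power), coherence, and band summaries.

#' Welch power spectral density
#'
#' Averaged modified periodogram with a Hann window. One-sided density
#' normalised so that `sum(power) * df` equals the signal variance per
#' parcel (~1 for z-scored data, hence "relative power").
#'
#' @param ts a [parcel_ts] (z-score first for relative power).
#' @param window_len window length in samples (default 500).
#' @param overlap overlap between windows in samples (default 250).
#' @return Object of class `power_spectrum`: list with `freq` (Hz) and
#'   `power` (frequency x parcel matrix).
#' @export
welch_psd <- function(ts, window_len = 500, overlap = 250) {
  x <- ts$data
  T <- nrow(x)
  if (window_len > T) stop("recording shorter than one Welch window")
  if (overlap >= window_len) stop("overlap must be smaller than window_len")
  step <- window_len - overlap
  starts <- seq(1L, T - window_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(window_len) / (window_len + 1))
  u <- sum(w^2)
  nf <- window_len %/% 2L + 1L
  acc <- matrix(0, nf, ncol(x))
  for (s in starts) {
    seg <- x[s:(s + window_len - 1L), , drop = FALSE] * w
    X <- mvfft(seg)[seq_len(nf), , drop = FALSE]
    acc <- acc + Mod(X)^2
  }
  pxx <- acc / (length(starts) * u * ts$fs)
  # one-sided: double everything except DC (and Nyquist for even n)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (window_len %% 2L == 0L) dbl[nf] <- 1
  pxx <- pxx * dbl
  freq <- (seq_len(nf) - 1L) * ts$fs / window_len
  structure(list(freq = freq, power = pxx, fs = ts$fs,
                 labels = ts$labels),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins (%.2f-%.2f Hz) x %d parcels\n",
              length(x$freq), min(x$freq), max(x$freq), ncol(x$power)))
  invisible(x)
}

band_bins <- function(freq, band) {
  sel <- freq >= band[1] & freq <= band[2]
  if (!any(sel)) stop("band contains no frequency bins")
  sel
}

#' Motor-parcel band power
#'
#' Mean over the given parcels of the mean in-band power.
#'
#' @param ps a `power_spectrum`.
#' @param motor_parcels parcel column indices (typically the two
#'   superior motor parcels).
#' @param band numeric length-2 Hz interval.
#' @return Scalar band power.
#' @export
motor_band_power <- function(ps, motor_parcels, band = c(16, 25.5)) {
  sel <- band_bins(ps$freq, band)
  mean(colMeans(ps$power[sel, motor_parcels, drop = FALSE]))
}

# DPSS (Slepian) tapers: eigenvectors of the symmetric tridiagonal
# matrix whose eigenvalue problem the discrete prolate spheroidal
# sequences solve (Percival & Walden formulation). Returns n x k matrix
# of unit-energy tapers ordered by decreasing concentration.
dpss_tapers <- function(n, k, nw) {
  W <- nw / n
  t0 <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * W)
  diag_off <- (t0[-1] * (n - t0[-1])) / 2
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), seq_len(n))] <- diag_main
  A[cbind(seq_len(n - 1), seq(2, n))] <- diag_off
  A[cbind(seq(2, n), seq_len(n - 1))] <- diag_off
  e <- eigen(A, symmetric = TRUE)
  tapers <- e$vectors[, seq_len(k), drop = FALSE]
  tapers <- tapers * rep(1 / sqrt(colSums(tapers^2)), each = n)
  # polarity convention: positive mean (even tapers) / positive first lobe
  for (j in seq_len(k)) {
    s <- sum(tapers[, j])
    if (abs(s) > 1e-12 && s < 0) tapers[, j] <- -tapers[, j]
    else if (abs(s) <= 1e-12 && tapers[2, j] < 0) tapers[, j] <- -tapers[, j]
  }
  tapers
}

# taper cache: dpss is deterministic and re-used heavily
.dpss_cache <- new.env(parent = emptyenv())
dpss_cached <- function(n, k, nw) {
  key <- paste(n, k, nw, sep = "_")
  if (is.null(.dpss_cache[[key]]))
    .dpss_cache[[key]] <- dpss_tapers(n, k, nw)
  .dpss_cache[[key]]
}

# Per-window multitaper spectra for all parcels. Returns list with
#   freq   : retained frequency grid
#   psd    : array [n_windows, n_freq, P] of per-window PSDs
#   fft    : array [n_freq, P, n_tapers, n_windows] of tapered FFTs
#            (kept only when keep_fft = TRUE, needed for cross-spectra)
#   starts : window start samples
multitaper_windows <- function(ts, window = 2, n_tapers = 7, nw = 4,
                               fmin = 1, fmax = 45, keep_fft = FALSE) {
  x <- ts$data
  fs <- ts$fs
  wl <- as.integer(round(window * fs))
  T <- nrow(x)
  if (wl > T) stop("multitaper window longer than the recording")
  P <- ncol(x)
  n_win <- T %/% wl
  tapers <- dpss_cached(wl, n_tapers, nw)
  nf_full <- wl %/% 2L + 1L
  freq_full <- (seq_len(nf_full) - 1L) * fs / wl
  sel <- which(freq_full >= fmin & freq_full <= fmax)
  freq <- freq_full[sel]
  nf <- length(sel)
  psd <- array(0, dim = c(n_win, nf, P))
  ffts <- if (keep_fft) array(0i, dim = c(nf, P, n_tapers, n_win)) else NULL
  scale <- 2 / (fs * n_tapers)  # one-sided density, mean over tapers
  starts <- (seq_len(n_win) - 1L) * wl + 1L
  for (w in seq_len(n_win)) {
    seg <- x[starts[w]:(starts[w] + wl - 1L), , drop = FALSE]
    acc <- matrix(0, nf, P)
    for (tp in seq_len(n_tapers)) {
      X <- mvfft(seg * tapers[, tp])[sel, , drop = FALSE]
      acc <- acc + Mod(X)^2
      if (keep_fft) ffts[, , tp, w] <- X
    }
    psd[w, , ] <- acc * scale
  }
  list(freq = freq, psd = psd, fft = ffts, starts = starts, wl = wl,
       n_tapers = n_tapers, fs = fs, scale = scale)
}

# window weights = mean of the per-sample weights within each window
window_weights <- function(weights, starts, wl) {
  vapply(starts, function(s) mean(weights[s:(s + wl - 1L)]), numeric(1))
}

#' Weighted multitaper power and cross-spectra
#'
#' Multitaper estimate (Slepian tapers, non-overlapping windows) in
#' which each window's cross-spectral matrix is combined with a weight
#' equal to the mean of the supplied per-sample weights inside the
#' window. With all weights 1 this is the ordinary multitaper estimate;
#' with posterior state probabilities as weights it yields
#' state-specific spectra; with a burst on/off indicator it yields
#' burst-locked spectra.
#'
#' @param ts a [parcel_ts].
#' @param weights per-sample weights in \[0, 1\]; `NULL` for unweighted.
#' @param window window length in seconds (default 2).
#' @param n_tapers number of Slepian tapers (default 7; with a 2-s
#'   window this corresponds to a time-bandwidth product of 4).
#' @param nw time-bandwidth product.
#' @param fmin,fmax frequency range in Hz.
#' @param compute_coherence also return the parcel x parcel coherence.
#' @return List with `freq`, `psd` (frequency x parcel), and when
#'   requested `coherence` (frequency x parcel x parcel array with unit
#'   diagonal).
#' @export
multitaper_cross_spectra <- function(ts, weights = NULL, window = 2,
                                     n_tapers = 7, nw = 4,
                                     fmin = 1, fmax = 45,
                                     compute_coherence = TRUE) {
  T <- n_samples(ts)
  if (is.null(weights)) weights <- rep(1, T)
  if (length(weights) != T) stop("weights length must equal sample count")
  if (any(weights < 0) || any(weights > 1 + 1e-9))
    stop("weights must lie in [0, 1]")
  mw <- multitaper_windows(ts, window, n_tapers, nw, fmin, fmax,
                           keep_fft = compute_coherence)
  wts <- window_weights(weights, mw$starts, mw$wl)
  if (sum(wts) <= 0) stop("all window weights are zero")
  wn <- wts / sum(wts)
  nf <- length(mw$freq)
  P <- ncol(ts$data)
  psd <- matrix(0, nf, P)
  for (w in seq_along(wn)) psd <- psd + wn[w] * mw$psd[w, , ]
  out <- list(freq = mw$freq, psd = psd, labels = ts$labels)
  if (compute_coherence) {
    S <- cross_spectral_matrix(mw, wn)
    out$csd <- S
    coh <- array(0, dim = dim(S))
    for (f in seq_len(nf)) {
      d <- Re(diag(S[f, , ]))
      denom <- outer(d, d)
      coh[f, , ] <- Mod(S[f, , ])^2 / denom
    }
    out$coherence <- coh
  }
  class(out) <- "mt_spectra"
  out
}

# weighted average cross-spectral matrix [nf, P, P] from multitaper
# windows; Hermitian by construction
cross_spectral_matrix <- function(mw, wn) {
  nf <- length(mw$freq)
  P <- dim(mw$fft)[2]
  S <- array(0i, dim = c(nf, P, P))
  for (w in seq_along(wn)) {
    if (wn[w] == 0) next
    for (tp in seq_len(mw$n_tapers)) {
      X <- mw$fft[, , tp, w, drop = FALSE]
      dim(X) <- c(nf, P)
      for (f in seq_len(nf))
        S[f, , ] <- S[f, , ] + (wn[w] * mw$scale) * outer(X[f, ], Conj(X[f, ]))
    }
  }
  S
}

#' Thresholded band-averaged coherence network
#'
#' Averages coherence over a frequency band and zeroes all edges below
#' the given percentile of the off-diagonal edge distribution (ties at
#' the threshold are kept). The diagonal is zeroed; output is symmetric.
#'
#' @param spectra an `mt_spectra` with a `coherence` slot.
#' @param band Hz interval over which to average.
#' @param percentile edge-retention percentile (default 97).
#' @return Symmetric parcel x parcel adjacency matrix.
#' @export
coherence_network <- function(spectra, band = c(2, 20), percentile = 97) {
  if (is.null(spectra$coherence)) stop("spectra carry no coherence")
  sel <- band_bins(spectra$freq, band)
  P <- dim(spectra$coherence)[2]
  adj <- matrix(0, P, P)
  for (f in which(sel)) adj <- adj + spectra$coherence[f, , ]
  adj <- adj / sum(sel)
  diag(adj) <- 0
  edges <- adj[upper.tri(adj)]
  thr <- quantile(edges, percentile / 100, names = FALSE)
  adj[adj < thr] <- 0
  diag(adj) <- 0
  adj
}
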