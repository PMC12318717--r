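# -- conventional amplitude-thresholding beta-burst analysis -----------

#' Hilbert amplitude envelope
#'
#' Magnitude of the analytic signal, computed via the frequency-domain
#' construction (positive frequencies doubled, negative zeroed).
#'
#' @param x numeric vector, typically a narrowband-filtered parcel time
#'   course.
#' @return Non-negative envelope of the same length.
#' @export
hilbert_envelope <- function(x) {
  if (!all(is.finite(x))) stop("input must be finite")
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}

#' Burst detection configuration
#'
#' @param band narrowband filter interval in Hz (default 18-25, the
#'   beta range used for motor bursts).
#' @param threshold_percentile amplitude-envelope percentile defining
#'   the burst threshold, per subject and parcel (default 75).
#' @param min_duration minimum burst duration in seconds; default one
#'   cycle of the band's low edge. A run qualifies when it is strictly
#'   longer than this, i.e. spans at least `floor(fs/band[1]) + 1`
#'   samples.
#' @param motor_parcels indices of the two motor parcels.
#' @return A `burst_config` list.
#' @export
burst_config <- function(band = c(18, 25), threshold_percentile = 75,
                         min_duration = 1 / band[1],
                         motor_parcels = c(1L, 2L)) {
  stopifnot(length(band) == 2L, band[1] > 0, band[2] > band[1])
  if (threshold_percentile <= 0 || threshold_percentile >= 100)
    stop("threshold_percentile must lie strictly between 0 and 100")
  if (min_duration <= 0) stop("min_duration must be positive")
  structure(list(band = band,
                 threshold_percentile = threshold_percentile,
                 min_duration = min_duration,
                 motor_parcels = motor_parcels),
            class = "burst_config")
}

# minimum run length in samples for duration strictly greater than
# min_duration seconds
min_burst_samples <- function(fs, min_duration) {
  floor(fs * min_duration) + 1L
}

#' Threshold an amplitude envelope into a burst track
#'
#' The threshold is the given percentile of the envelope over retained
#' (unmasked) samples. Supra-threshold runs strictly longer than
#' `min_duration` become bursts; masked samples can never belong to a
#' burst (runs truncated at mask boundaries are kept when the retained
#' portion still satisfies the duration rule).
#'
#' @param envelope non-negative numeric vector.
#' @param fs sampling rate in Hz.
#' @param config a [burst_config].
#' @param mask optional logical retention mask.
#' @return A [binary_track] with attributes `threshold` and
#'   `min_samples`.
#' @export
detect_bursts <- function(envelope, fs, config = burst_config(),
                          mask = NULL) {
  n <- length(envelope)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (length(mask) != n) stop("mask length must match envelope")
  if (!any(mask)) stop("all samples are masked")
  thr <- quantile(envelope[mask], config$threshold_percentile / 100,
                  names = FALSE)
  on <- envelope > thr & mask
  mn <- min_burst_samples(fs, config$min_duration)
  ev <- track_events(on)
  short <- ev[ev$offset - ev$onset + 1L < mn, , drop = FALSE]
  for (i in seq_len(nrow(short)))
    on[short$onset[i]:short$offset[i]] <- FALSE
  tr <- binary_track(on, fs, "burst")
  attr(tr, "threshold") <- thr
  attr(tr, "min_samples") <- mn
  tr
}

#' Motor-cortical beta bursts from a parcel recording
#'
#' Full conventional burst analysis: narrowband filter each motor
#' parcel, Hilbert envelope, per-parcel percentile threshold, duration
#' rule, then bilateral combination by logical OR.
#'
#' @param ts a [parcel_ts] (preprocessed).
#' @param config a [burst_config] naming the motor parcels.
#' @param mask optional logical retention mask.
#' @return List with per-parcel `tracks`, the `combined` bilateral
#'   [binary_track], and the inter-parcel `overlap` percentage
#'   (intersection over union).
#' @export
detect_motor_bursts <- function(ts, config = burst_config(), mask = NULL) {
  tracks <- lapply(config$motor_parcels, function(p) {
    env <- hilbert_envelope(
      fir_bandpass(ts$data[, p], ts$fs, config$band[1], config$band[2],
                   trans_bw = 3))
    detect_bursts(env, ts$fs, config, mask)
  })
  names(tracks) <- ts$labels[config$motor_parcels]
  combined <- Reduce(combine_bilateral, tracks)
  combined$label <- "burst"
  list(tracks = tracks, combined = combined,
       overlap = interparcel_overlap(tracks[[1]], tracks[[2]]))
}

#' Beta-power change during bursts
#'
#' Multitaper in-band motor-parcel power with burst-on weights minus
#' the mean of the on- and off-weighted estimates, so that on- and
#' off-period changes are antisymmetric around zero.
#'
#' @param ts a [parcel_ts].
#' @param track burst [binary_track] aligned with `ts`.
#' @param motor_parcels parcel indices to average.
#' @param band Hz interval (default 16-25.5).
#' @param mask optional retention mask.
#' @param ... passed to [multitaper_cross_spectra()].
#' @return Scalar power change.
#' @export
burst_beta_power <- function(ts, track, motor_parcels, band = c(16, 25.5),
                             mask = NULL, ...) {
  on <- track$on
  if (!is.null(mask)) on <- on & mask
  off <- !track$on
  if (!is.null(mask)) off <- off & mask
  if (!any(on) || !any(off))
    stop("burst track is degenerate (all on or all off)")
  # one pass over the windows; the on- and off-weighted estimates are
  # different weightings of the same per-window spectra
  mw <- multitaper_windows(ts, ...)
  bp <- function(w) {
    wts <- window_weights(as.numeric(w), mw$starts, mw$wl)
    if (sum(wts) <= 0) stop("all window weights are zero")
    wn <- wts / sum(wts)
    sel <- band_bins(mw$freq, band)
    acc <- 0
    for (j in seq_along(wn))
      acc <- acc + wn[j] *
        mean(mw$psd[j, sel, motor_parcels, drop = FALSE])
    acc
  }
  b_on <- bp(on)
  b_on - mean(c(b_on, bp(off)))
}
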