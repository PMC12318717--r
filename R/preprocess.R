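# Zero-phase FIR band-pass: Hamming-window design (signal::fir1) applied
# forwards and backwards (overlap-add FFT filtering, signal::fftfilt).
# Filter order scales with the transition bandwidth (3.3 / tbw cycles,
# the Hamming-window rule of thumb), giving > 50 dB stop-band
# attenuation per pass; the reversed second pass cancels the phase.
fir_bandpass <- function(x, fs, low, high, trans_bw = 2) {
  n <- ceiling(3.3 * fs / trans_bw)
  n <- min(n, floor((length(x) - 1) / 3))
  if (n %% 2L == 1L) n <- n + 1L
  if (n < 8L) stop("signal too short to filter")
  b <- as.numeric(signal::fir1(n, c(low, high) / (fs / 2), type = "pass"))
  y <- signal::fftfilt(b, c(x, numeric(n)))
  y <- rev(signal::fftfilt(b, rev(y)))
  y[seq_along(x)]
}

apply_cols <- function(x, f, ...) {
  out <- vapply(seq_len(ncol(x)), function(j) f(x[, j], ...),
                numeric(nrow(x)))
  dimnames(out) <- dimnames(x)
  out
}

#' Band-pass filter and downsample parcel time courses
#'
#' Zero-phase FIR band-pass (Hamming-window design, applied forwards and
#' backwards) followed by integer-factor decimation. Because the
#' band-pass already removes energy above the target Nyquist frequency,
#' decimation is plain subsampling.
#'
#' @param ts a [parcel_ts].
#' @param low,high band edges in Hz; must satisfy
#'   `0 < low < high < fs/2` and `high < target_fs/2`.
#' @param target_fs output sampling rate; `fs` must be an integer
#'   multiple.
#' @param trans_bw filter transition bandwidth in Hz.
#' @return A [parcel_ts] sampled at `target_fs`.
#' @export
bandpass_downsample <- function(ts, low = 1, high = 45,
                                target_fs = ts$fs, trans_bw = 2) {
  fs <- ts$fs
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band must satisfy 0 < low < high < fs/2")
  if (target_fs > fs) stop("target_fs cannot exceed fs")
  if (target_fs < fs && fs %% target_fs != 0)
    stop("fs must be an integer multiple of target_fs")
  if (high >= target_fs / 2)
    stop("band edge 'high' must lie below the target Nyquist frequency")
  y <- apply_cols(ts$data, fir_bandpass, fs = fs, low = low, high = high,
                  trans_bw = trans_bw)
  if (target_fs < fs) {
    step <- fs / target_fs
    y <- y[seq(1L, nrow(y), by = step), , drop = FALSE]
  }
  parcel_ts(y, target_fs, ts$labels)
}

excess_kurtosis <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)
  mean((x - m)^4) / v^2 - 3
}

#' Generalized extreme studentized deviate (GESD) outlier test
#'
#' Rosner's recursive two-sided test for up to `max_outliers` outliers
#' in a univariate sample. With `max_outliers = 1` it reduces to the
#' Grubbs test.
#'
#' @param x numeric vector (length >= 3, finite).
#' @param max_outliers upper bound on the number of outliers tested.
#' @param alpha significance level of each extreme studentized deviate.
#' @return Integer vector of outlier indices into `x` (possibly empty).
#' @export
gesd_outliers <- function(x, max_outliers, alpha = 0.05) {
  if (length(x) < 3L) stop("GESD requires at least 3 observations")
  if (!all(is.finite(x))) stop("GESD metric values must be finite")
  max_outliers <- min(max_outliers, length(x) - 2L)
  if (max_outliers < 1L) return(integer(0))
  idx <- seq_along(x)
  removed <- integer(0)
  R <- lambda <- numeric(max_outliers)
  for (i in seq_len(max_outliers)) {
    s <- sd(x[idx])
    if (s == 0) { R[i] <- 0 } else {
      dev <- abs(x[idx] - mean(x[idx]))
      j <- which.max(dev)
      R[i] <- dev[j] / s
      removed[i] <- idx[j]
      idx <- idx[-j]
    }
    n <- length(x) - i + 1L
    p <- 1 - alpha / (2 * n)
    tq <- qt(p, n - 2L)
    lambda[i] <- (n - 1L) * tq / sqrt((n - 2L + tq^2) * n)
  }
  last <- which(R > lambda)
  if (length(last) == 0L) return(integer(0))
  sort(removed[seq_len(max(last))])
}

#' Flag outlier segments of a recording
#'
#' Splits the recording into fixed-length segments, summarises each
#' segment by its variance and its excess kurtosis (each computed per
#' parcel, then averaged across parcels), runs the two-sided GESD test
#' on each summary and unions the flags. All samples of a flagged
#' segment are marked bad. A trailing partial segment is never tested
#' (GESD needs equal-length segments) and stays retained.
#'
#' @param ts a [parcel_ts].
#' @param segment_len segment length in seconds (default 10).
#' @param metrics which segment summaries to test.
#' @param alpha GESD significance level.
#' @param max_outliers upper bound on flagged segments per metric;
#'   default 20% of the number of complete segments.
#' @return Logical sample mask (`TRUE` = retained) with attributes
#'   `flagged_fraction` and `flagged_segments`.
#' @export
detect_bad_segments <- function(ts, segment_len = 10,
                                metrics = c("variance", "kurtosis"),
                                alpha = 0.05, max_outliers = NULL) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  seg_n <- segment_len * ts$fs
  if (seg_n != round(seg_n)) stop("segment_len * fs must be an integer")
  seg_n <- as.integer(seg_n)
  T <- n_samples(ts)
  n_seg <- T %/% seg_n
  if (n_seg < 3L) stop("need at least 3 complete segments for GESD")
  if (is.null(max_outliers)) max_outliers <- max(1L, floor(0.2 * n_seg))

  flagged <- logical(n_seg)
  for (m in metrics) {
    f <- if (m == "variance") var else excess_kurtosis
    vals <- vapply(seq_len(n_seg), function(s) {
      rows <- ((s - 1L) * seg_n + 1L):(s * seg_n)
      mean(apply(ts$data[rows, , drop = FALSE], 2, f))
    }, numeric(1))
    flagged[gesd_outliers(vals, max_outliers, alpha)] <- TRUE
  }
  mask <- rep(TRUE, T)
  mask[which(rep(flagged, each = seg_n))] <- FALSE
  structure(mask,
            flagged_fraction = sum(flagged) / n_seg,
            flagged_segments = which(flagged))
}
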