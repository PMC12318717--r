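#' Binary activation track
#'
#' Per-sample on/off time course at a known sampling rate. Used for
#' beta bursts, HMM state visits and network-associated beta bursts.
#'
#' @param on logical (or 0/1) vector of activations.
#' @param fs sampling rate in Hz.
#' @param label provenance label, e.g. `"burst"` or `"state_3"`.
#' @return Object of class `binary_track`.
#' @export
binary_track <- function(on, fs, label = "track") {
  on <- as.logical(on)
  if (length(on) == 0L || anyNA(on)) stop("track must be non-empty logical")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  structure(list(on = on, fs = fs, label = label), class = "binary_track")
}

#' @export
print.binary_track <- function(x, ...) {
  cat(sprintf("<binary_track '%s'> %d samples @ %g Hz, FO %.3f\n",
              x$label, length(x$on), x$fs, mean(x$on)))
  invisible(x)
}

#' @export
length.binary_track <- function(x) length(x$on)

# run-length events of a logical vector: data.frame(onset, offset) in
# sample indices, inclusive
track_events <- function(on) {
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(onset = starts[keep], offset = ends[keep])
}

#' Dynamics metrics of a binary track
#'
#' Computes the standard occupancy statistics of an on/off time course:
#' fractional occupancy (FO, fraction of retained time spent on), mean
#' lifetime (mean duration of contiguous on-runs, s), mean interval
#' (mean gap between consecutive events, s), rate (events per second of
#' retained time) and event count. The identity `FO = rate x mean
#' lifetime` holds exactly by construction. Masked samples are treated
#' as off and excluded from the retained-time denominator.
#'
#' @param track a [binary_track] (or logical vector with `fs` supplied).
#' @param mask optional logical vector, `TRUE` = retained sample.
#' @param fs sampling rate, only needed when `track` is a bare vector.
#' @return One-row `data.frame` with columns `fo`, `mean_lifetime`,
#'   `mean_interval`, `rate`, `n_events`. Lifetime is `NA` when there
#'   are no events; interval is `NA` with fewer than two events.
#' @export
track_metrics <- function(track, mask = NULL, fs = NULL) {
  if (inherits(track, "binary_track")) {
    on <- track$on
    fs <- track$fs
  } else {
    on <- as.logical(track)
    if (is.null(fs)) stop("fs required for bare logical tracks")
  }
  if (is.null(mask)) mask <- rep(TRUE, length(on))
  if (length(mask) != length(on)) stop("mask length must match track")
  on <- on & mask
  retained <- sum(mask)
  if (retained == 0L) stop("all samples masked")

  ev <- track_events(on)
  n <- nrow(ev)
  fo <- sum(on) / retained
  lifetimes <- (ev$offset - ev$onset + 1L) / fs
  intervals <- if (n >= 2L) (ev$onset[-1L] - ev$offset[-n] - 1L) / fs else numeric(0)
  data.frame(
    fo = fo,
    mean_lifetime = if (n > 0L) mean(lifetimes) else NA_real_,
    mean_interval = if (n >= 2L) mean(intervals) else NA_real_,
    rate = n / (retained / fs),
    n_events = n
  )
}

#' Combine two activation tracks by logical OR
#'
#' Used to merge left/right motor-parcel burst tracks into one bilateral
#' burst time course (a burst is counted when it occurs in at least one
#' motor parcel).
#'
#' @param left,right [binary_track]s of equal length and sampling rate.
#' @return A [binary_track].
#' @export
combine_bilateral <- function(left, right) {
  if (length(left$on) != length(right$on))
    stop("tracks must have equal length")
  if (left$fs != right$fs) stop("tracks must share the sampling rate")
  binary_track(left$on | right$on, left$fs,
               paste0(left$label, "|", right$label))
}

#' Overlap between two activation tracks
#'
#' Intersection-over-union of the on-samples, reported as a percentage.
#' Intersection-over-left and intersection-over-right are attached as
#' attributes for reference.
#'
#' @param left,right [binary_track]s of equal length.
#' @return Percentage in \[0, 100\]; `NA` when both tracks are empty.
#' @export
interparcel_overlap <- function(left, right) {
  if (length(left$on) != length(right$on))
    stop("tracks must have equal length")
  inter <- sum(left$on & right$on)
  uni <- sum(left$on | right$on)
  if (uni == 0L) return(structure(NA_real_, over_left = NA_real_,
                                  over_right = NA_real_))
  structure(100 * inter / uni,
            over_left = if (sum(left$on) > 0) 100 * inter / sum(left$on) else NA_real_,
            over_right = if (sum(right$on) > 0) 100 * inter / sum(right$on) else NA_real_)
}

# circularly shift a logical/integer vector by s samples (positive =
# delay); used by the co-occurrence null
circular_shift <- function(x, s) {
  n <- length(x)
  s <- ((s %% n) + n) %% n
  if (s == 0) return(x)
  c(x[(n - s + 1L):n], x[1L:(n - s)])
}
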