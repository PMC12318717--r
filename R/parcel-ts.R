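#' Parcel time-series container
#'
#' A `parcel_ts` holds one subject's source-space recording: a numeric
#' matrix with one row per sample and one column per cortical parcel,
#' together with the sampling rate and parcel labels.
#'
#' @param data numeric matrix, samples x parcels.
#' @param fs sampling rate in Hz.
#' @param labels character vector of parcel names; defaults to
#'   `colnames(data)` or `parcel_1 ... parcel_P`.
#' @return An object of class `parcel_ts`.
#' @export
parcel_ts <- function(data, fs, labels = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data)))
    stop("parcel data must be a finite numeric matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  if (is.null(labels)) {
    labels <- colnames(data)
    if (is.null(labels)) labels <- paste0("parcel_", seq_len(ncol(data)))
  }
  if (length(labels) != ncol(data))
    stop("labels length must equal the number of parcels")
  colnames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels),
            class = "parcel_ts")
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("<parcel_ts> %d samples x %d parcels @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs))
  invisible(x)
}

#' @export
dim.parcel_ts <- function(x) dim(x$data)

n_samples <- function(ts) nrow(ts$data)

as_parcel_ts <- function(x, fs) {
  if (inherits(x, "parcel_ts")) x else parcel_ts(x, fs)
}

subset_parcels <- function(ts, parcels) {
  parcel_ts(ts$data[, parcels, drop = FALSE], ts$fs, ts$labels[parcels])
}

#' Z-standardise each parcel time course
#'
#' Centres and scales every parcel to mean 0, variance 1. Spectra of
#' standardised data integrate to ~1 per parcel, which is what makes
#' Welch estimates comparable across subjects ("relative power").
#'
#' @param ts a [parcel_ts].
#' @return A [parcel_ts] with standardised columns.
#' @export
zscore_parcels <- function(ts) {
  x <- ts$data
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("cannot z-score constant parcel(s): ",
         paste(ts$labels[sds == 0], collapse = ", "))
  x <- scale(x, center = TRUE, scale = sds)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  parcel_ts(x, ts$fs, ts$labels)
}
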