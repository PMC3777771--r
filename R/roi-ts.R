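#' Per-ROI source time series
#'
#' A light container for source-space recordings: a channels x samples matrix
#' with one row per cortical ROI (or per candidate voxel when a ROI is
#' represented by several voxels), a sampling rate, and an optional band tag
#' set once the series have been band-filtered.
#'
#' @param data Numeric matrix, channels x samples.
#' @param labels Character vector of channel labels, one per row.
#' @param rate Sampling rate in Hz (> 0).
#' @param band Optional band name or `c(low, high)` (see [get_band()]).
#' @param roi Optional character vector mapping each channel to its parent
#'   ROI, used when channels are candidate voxels; defaults to `labels`.
#' @return An object of class `roi_ts`.
#' @export
roi_ts <- function(data, labels, rate, band = NULL, roi = NULL) {
  data <- as.matrix(data)
  dimnames(data) <- NULL  # labels are authoritative; keep storage canonical
  if (!is.numeric(data)) abort("`data` must be a numeric matrix")
  if (length(labels) != nrow(data)) {
    abort(sprintf("label count (%d) must equal channel count (%d)",
                  length(labels), nrow(data)))
  }
  if (anyDuplicated(labels)) abort("channel labels must be unique")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    abort("`rate` must be a single positive number (Hz)")
  }
  roi <- roi %||% as.character(labels)
  if (length(roi) != nrow(data)) abort("`roi` must have one entry per channel")
  band_tbl <- if (is.null(band)) NULL else get_band(band)
  structure(
    list(data = data, labels = as.character(labels), rate = rate,
         band = band_tbl, roi = roi),
    class = "roi_ts"
  )
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> %d channels x %d samples @ %g Hz%s\n",
              nrow(x$data), ncol(x$data), x$rate,
              if (is.null(x$band)) "" else paste0(" [", x$band$band, "]")))
  invisible(x)
}

#' @export
dim.roi_ts <- function(x) dim(x$data)

#' Epoched band-limited signals
#'
#' @param epochs List of channels x samples matrices of equal shape.
#' @param labels Channel labels shared by every epoch.
#' @param rate Sampling rate in Hz.
#' @param band Optional band tag (see [get_band()]).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, labels, rate, band = NULL) {
  if (length(epochs) > 0) {
    dims <- vapply(epochs, dim, integer(2))
    if (any(dims[1, ] != length(labels)) || length(unique(dims[2, ])) > 1) {
      abort("all epochs must share channel count and length")
    }
  }
  structure(
    list(epochs = epochs, labels = as.character(labels), rate = rate,
         band = if (is.null(band)) NULL else get_band(band)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  len <- if (length(x$epochs)) ncol(x$epochs[[1]]) else 0L
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              length(x$epochs), length(x$labels), len, x$rate))
  invisible(x)
}
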