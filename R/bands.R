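#' Canonical analysis frequency bands
#'
#' The six bands used throughout the pipeline: delta (0.5--4 Hz), theta
#' (4--8 Hz), lower alpha (8--10 Hz), upper alpha (10--13 Hz), beta
#' (13--30 Hz) and lower gamma (30--48 Hz).
#'
#' @return A tibble with columns `band`, `low`, `high` (Hz).
#' @export
#' @examples
#' freq_bands()
freq_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "lower_alpha", "upper_alpha", "beta", "lower_gamma"),
    low  = c(0.5, 4, 8, 10, 13, 30),
    high = c(4, 8, 10, 13, 30, 48)
  )
}

#' Look up one frequency band
#'
#' @param band A band name from [freq_bands()], or a numeric `c(low, high)`
#'   pair in Hz for an ad-hoc band.
#' @return A one-row tibble with `band`, `low`, `high`.
#' @export
get_band <- function(band) {
  if (is.data.frame(band) && all(c("band", "low", "high") %in% names(band))) {
    return(band)  # already a band row: idempotent
  }
  if (is.numeric(band)) {
    if (length(band) != 2 || band[1] >= band[2]) {
      abort("a numeric band must be c(low, high) with low < high")
    }
    lo <- band[1]; hi <- band[2]
    nm <- freq_bands()$band[freq_bands()$low == lo & freq_bands()$high == hi]
    if (length(nm) != 1) nm <- sprintf("%g-%gHz", lo, hi)
    return(tibble::tibble(band = nm, low = lo, high = hi))
  }
  tbl <- freq_bands()
  hit <- tbl[tbl$band == band, ]
  if (nrow(hit) != 1) {
    abort(sprintf("unknown band '%s'; expected one of %s",
                  band, paste(tbl$band, collapse = ", ")))
  }
  hit
}
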