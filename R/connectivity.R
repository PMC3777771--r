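#' Analytic signal via the one-sided spectrum
#'
#' Computes the discrete analytic signal of a real series by zeroing the
#' negative-frequency half of its FFT (doubling strictly positive
#' frequencies, keeping DC and Nyquist), then inverse-transforming. The
#' imaginary part is the Hilbert transform of the input.
#'
#' @param x Numeric vector.
#' @return Complex vector the same length as `x`.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2) abort("series too short for an analytic signal")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited series
#'
#' Phase of the analytic signal at each sample, in radians within
#' \eqn{[-\pi, \pi]}. A pure sinusoid yields a phase advancing linearly at
#' its angular frequency (modulo \eqn{2\pi}).
#'
#' @param x Numeric vector of at least 64 samples.
#' @return Numeric vector of phases in \eqn{[-\pi, \pi]}.
#' @export
instantaneous_phase <- function(x) {
  if (length(x) < 64) abort("series must have at least 64 samples")
  if (all(x == 0)) abort("phase undefined for an all-zero series")
  Arg(analytic_signal(x))
}

#' Phase lag index of two phase series
#'
#' The PLI is the absolute mean of the sign of the sine of the instantaneous
#' phase difference, \eqn{|\langle \mathrm{sign}\,\sin \Delta\phi(t_k)\rangle|},
#' with the phase difference taken in \eqn{[-\pi, \pi]}. It ranges from 0 (no
#' consistent nonzero-lag phase relation) to 1 (total synchronization at a
#' fixed nonzero lag) and is insensitive to zero-lag (volume-conducted)
#' coupling, since `sign(sin(0)) = 0` and symmetric phase-difference
#' distributions cancel. A fraction of samples at each end is discarded
#' before averaging to suppress Hilbert edge effects.
#'
#' @param phase_a,phase_b Equal-length phase vectors (radians).
#' @param edge_trim Fraction of samples dropped at each end, in `[0, 0.25]`
#'   (default 0.05).
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' t <- seq(0, 2, length.out = 512)
#' pli_pair(2 * pi * 10 * t, 2 * pi * 10 * t - pi / 2)  # constant lag: 1
pli_pair <- function(phase_a, phase_b, edge_trim = 0.05) {
  if (length(phase_a) != length(phase_b)) {
    abort(sprintf("phase series lengths differ: %d vs %d",
                  length(phase_a), length(phase_b)))
  }
  if (edge_trim < 0 || edge_trim > 0.25) abort("`edge_trim` must be in [0, 0.25]")
  n <- length(phase_a)
  k <- floor(n * edge_trim)
  keep <- (k + 1):(n - k)
  d <- phase_a[keep] - phase_b[keep]
  abs(mean(sign(sin(d))))
}

# All-channel instantaneous phases in one mvfft pass (rows = channels).
phase_matrix <- function(blk) {
  n <- ncol(blk)
  if (n < 64) abort("epochs must have at least 64 samples")
  if (any(rowSums(abs(blk)) == 0)) abort("phase undefined for an all-zero channel")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(t(blk))
  Z <- stats::mvfft(X * h, inverse = TRUE)
  t(Arg(Z))
}

#' PLI connectivity matrix
#'
#' One symmetric ROI x ROI phase-lag-index matrix from an epoch set: per
#' epoch, instantaneous phases per channel and the PLI for every unordered
#' channel pair; the final value is by default the arithmetic mean of the
#' per-epoch PLIs (avoiding phase discontinuities at epoch boundaries),
#' switchable to estimation over the concatenated epochs. The diagonal is 0
#' by convention and excluded from all averages.
#'
#' @param epochs An [epoch_set()] with at least one epoch and two channels.
#' @param edge_trim Passed to [pli_pair()].
#' @param epoch_mode `"average"` (default) or `"concatenate"`.
#' @return Object of class `pli_matrix`: fields `values` (symmetric matrix in
#'   `[0, 1]`), `roi_labels`, `band`, `n_epochs_averaged`.
#' @export
pli_matrix <- function(epochs, edge_trim = 0.05,
                       epoch_mode = c("average", "concatenate")) {
  stopifnot(inherits(epochs, "epoch_set"))
  epoch_mode <- match.arg(epoch_mode)
  if (length(epochs$epochs) == 0) abort("PLI undefined for zero epochs")
  nch <- length(epochs$labels)
  if (nch < 2) abort("need at least two channels")

  blocks <- epochs$epochs
  if (epoch_mode == "concatenate") {
    blocks <- list(do.call(cbind, blocks))
  }
  pairs <- combn(nch, 2)
  acc <- matrix(0, nch, nch)
  for (blk in blocks) {
    ph <- phase_matrix(blk)
    n <- ncol(ph)
    d <- ph[pairs[1, ], , drop = FALSE] - ph[pairs[2, ], , drop = FALSE]
    kk <- floor(n * edge_trim)
    keep <- (kk + 1):(n - kk)
    v <- abs(rowMeans(sign(sin(d[, keep, drop = FALSE]))))
    m <- matrix(0, nch, nch)
    m[t(pairs)] <- v
    acc <- acc + m + t(m)
  }
  vals <- acc / length(blocks)
  dimnames(vals) <- list(epochs$labels, epochs$labels)
  structure(
    list(values = vals, roi_labels = epochs$labels, band = epochs$band,
         n_epochs_averaged = length(blocks)),
    class = "pli_matrix"
  )
}

#' @export
print.pli_matrix <- function(x, ...) {
  cat(sprintf("<pli_matrix> %d ROIs%s, %d epoch(s) averaged; mean off-diag PLI %.3f\n",
              length(x$roi_labels),
              if (is.null(x$band)) "" else paste0(" [", x$band$band, "]"),
              x$n_epochs_averaged, mean_pli(x)))
  invisible(x)
}

#' Tidy a connectivity matrix into an edge list
#'
#' @param x A `pli_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per unordered ROI pair: `roi_a`, `roi_b`, `pli`.
#' @method tidy pli_matrix
#' @export
tidy.pli_matrix <- function(x, ...) {
  p <- combn(length(x$roi_labels), 2)
  tibble::tibble(roi_a = x$roi_labels[p[1, ]],
                 roi_b = x$roi_labels[p[2, ]],
                 pli = x$values[t(p)])
}

#' Mean PLI over all pairs or a ROI subset
#'
#' Averages the within-subset unordered pairs only: connections from the
#' subset to the rest of the matrix are excluded, which is how sub-network
#' connectivity is defined. With no subset, the mean runs over all unordered
#' pairs (3003 for the 78-ROI registry).
#'
#' @param matrix A `pli_matrix`.
#' @param roi_subset Optional character vector of at least two labels present
#'   in the matrix.
#' @return Scalar mean PLI.
#' @export
mean_pli <- function(matrix, roi_subset = NULL) {
  stopifnot(inherits(matrix, "pli_matrix"))
  labels <- matrix$roi_labels
  if (is.null(roi_subset)) {
    idx <- seq_along(labels)
  } else {
    unknown <- setdiff(roi_subset, labels)
    if (length(unknown) > 0) {
      abort(sprintf("unknown label(s): %s", paste(unknown, collapse = ", ")))
    }
    if (length(roi_subset) < 2) abort("subset must contain at least two ROIs")
    idx <- match(roi_subset, labels)
  }
  sub <- matrix$values[idx, idx, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Reorder a connectivity matrix to a reference label ordering
#'
#' Matrices are never silently reindexed downstream; this is the explicit
#' realignment operation for matrices whose labels match a registry but in a
#' different order.
#'
#' @param matrix A `pli_matrix`.
#' @param labels Target ordering (a permutation of the matrix labels).
#' @return A `pli_matrix` in the requested order.
#' @export
realign_matrix <- function(matrix, labels) {
  stopifnot(inherits(matrix, "pli_matrix"))
  if (!setequal(labels, matrix$roi_labels) ||
      length(labels) != length(matrix$roi_labels)) {
    abort("`labels` must be a permutation of the matrix labels")
  }
  idx <- match(labels, matrix$roi_labels)
  matrix$values <- matrix$values[idx, idx]
  matrix$roi_labels <- matrix$roi_labels[idx]
  matrix
}
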