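# Monte-Carlo calibration of the coupling -> PLI map.
# Rows: shared-component fraction; columns: pairwise phase lag (folded to
# [0, pi/2]). Cells are mean pipeline PLI over 300 simulated 4096-sample
# pairs at 312.5 Hz in the 8-10 Hz band with unit white noise, made
# non-decreasing along the coupling axis. The weak dependence of the c = 0
# floor on epoch length is discussed in the methods vignette.
pli_calibration <- local({
  tab <- rbind(
    c(0.1413, 0.1398, 0.1440, 0.1356, 0.1381),
    c(0.1472, 0.1398, 0.1508, 0.1508, 0.1418),
    c(0.1472, 0.1488, 0.1508, 0.1632, 0.1614),
    c(0.1472, 0.1533, 0.1588, 0.1661, 0.1847),
    c(0.1472, 0.1533, 0.1871, 0.1921, 0.2195),
    c(0.1472, 0.1748, 0.2178, 0.2811, 0.3148),
    c(0.1472, 0.1883, 0.2999, 0.3629, 0.4103),
    c(0.1472, 0.2262, 0.3701, 0.4766, 0.4771),
    c(0.1472, 0.3161, 0.5276, 0.6061, 0.6517),
    c(0.1472, 0.4414, 0.6723, 0.7716, 0.7987),
    c(0.1472, 0.9188, 0.9742, 0.9841, 0.9879)
  )
  dimnames(tab) <- NULL
  list(
    c_grid = c(0.0, 0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5, 0.65, 0.8, 1.0),
    d_grid = c(0.000000, 0.392699, 0.785398, 1.178097, 1.570796),
    pli = tab
  )
})

# Bilinear interpolation of the calibration table at (coupling, lag).
interp_calibration <- function(coupling, lag) {
  cg <- pli_calibration$c_grid
  dg <- pli_calibration$d_grid
  M <- pli_calibration$pli
  d <- abs(lag) %% pi
  d <- min(d, pi - d)
  cc <- min(max(coupling, cg[1]), cg[length(cg)])
  d <- min(max(d, dg[1]), dg[length(dg)])
  i <- max(2, min(findInterval(cc, cg, all.inside = TRUE) + 1, length(cg)))
  j <- max(2, min(findInterval(d, dg, all.inside = TRUE) + 1, length(dg)))
  wc <- (cc - cg[i - 1]) / (cg[i] - cg[i - 1])
  wd <- (d - dg[j - 1]) / (dg[j] - dg[j - 1])
  (1 - wc) * (1 - wd) * M[i - 1, j - 1] + wc * (1 - wd) * M[i, j - 1] +
    (1 - wc) * wd * M[i - 1, j] + wc * wd * M[i, j]
}

#' Expected mean within-network PLI for a given coupling
#'
#' For a network of `m` members whose phase offsets are evenly spaced over
#' `(0, pi)`, the expected mean over the `choose(m, 2)` within-network pairs
#' of the calibrated pairwise PLI at shared-component fraction `coupling`.
#'
#' @param coupling Shared-component fraction in `[0, 1]`.
#' @param m Network size (>= 2).
#' @return Expected mean network PLI.
#' @export
network_pli_from_coupling <- function(coupling, m) {
  ks <- seq_len(m - 1)
  w <- m - ks
  vals <- vapply(ks * pi / m, function(d) interp_calibration(coupling, d),
                 numeric(1))
  sum(w * vals) / sum(w)
}

#' Coupling required for a target mean within-network PLI
#'
#' Inverts [network_pli_from_coupling()] by root finding; targets at or
#' below the finite-sample null floor give 0 and targets beyond the fully
#' coupled value give 1.
#'
#' @param target Desired mean within-network PLI.
#' @param m Network size.
#' @return Shared-component fraction in `[0, 1]`.
#' @export
coupling_for_network_pli <- function(target, m) {
  lo <- network_pli_from_coupling(0, m)
  hi <- network_pli_from_coupling(1, m)
  if (target <= lo) return(0)
  if (target >= hi) return(1)
  stats::uniroot(function(c) network_pli_from_coupling(c, m) - target,
                 c(0, 1), tol = 1e-6)$root
}
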