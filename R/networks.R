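#' Connectivity matrices for every recording of a cohort
#'
#' Maps the preprocessing + PLI chain over every subject/timepoint recording
#' and every requested band: decimation (if `factor > 1`), representative-
#' voxel collapse when recordings carry voxel groups, zero-phase band
#' filtering, epoching, and the PLI matrix.
#'
#' @param cohort A `meg_cohort` from [generate_cohort()] (or any tibble with
#'   `subject`, `timepoint` and a `ts` list-column of [roi_ts()] passed via
#'   `recordings`).
#' @param bands Character vector of band names (default: the cohort's effect
#'   band).
#' @param factor Decimation factor applied before filtering (default 1).
#' @param edge_trim,epoch_mode Passed to [pli_matrix()].
#' @return Tibble: `subject`, `timepoint`, `band`, `matrix` (list of
#'   `pli_matrix`).
#' @export
cohort_connectivity <- function(cohort, bands = NULL, factor = 1,
                                edge_trim = 0.05, epoch_mode = "average") {
  recs <- if (inherits(cohort, "meg_cohort")) cohort$recordings else cohort
  if (is.null(bands)) {
    bands <- if (inherits(cohort, "meg_cohort")) cohort$spec$effect_band else
      abort("`bands` must be given when `cohort` is a plain recordings table")
  }
  n_ep <- if (inherits(cohort, "meg_cohort")) cohort$spec$n_epochs else 5
  ep_len <- if (inherits(cohort, "meg_cohort")) cohort$spec$epoch_length else 4096
  out <- tidyr::expand_grid(dplyr::select(recs, "subject", "timepoint"),
                            band = bands)
  out <- dplyr::left_join(out, recs, by = c("subject", "timepoint"))
  out$matrix <- purrr::map2(out$ts, out$band, function(ts, b) {
    ep <- preprocess_recording(ts, b, factor = factor,
                               n_epochs = n_ep,
                               epoch_length = ep_len / max(factor, 1))
    pli_matrix(ep, edge_trim = edge_trim, epoch_mode = epoch_mode)
  })
  dplyr::select(out, "subject", "timepoint", "band", "matrix")
}

#' Mean PLI per resting-state network for every connectivity matrix
#'
#' One row per (subject, timepoint, band, network) with the mean PLI over
#' that network's within-network ROI pairs; optionally also a `"global"` row
#' per (subject, timepoint, band) averaging all unordered pairs. Matrices
#' whose label ordering disagrees with the first matrix are rejected, never
#' silently reindexed (use [realign_matrix()] first).
#'
#' @param matrices Tibble from [cohort_connectivity()] (columns `subject`,
#'   `timepoint`, `band`, `matrix`).
#' @param networks Named list of member-label vectors, e.g.
#'   `load_rsn_config()$networks`.
#' @param include_global Add `"global"` all-pairs rows (default FALSE).
#' @return Tibble: `subject`, `timepoint`, `band`, `network`, `mean_pli`.
#' @export
summarize_rsns <- function(matrices, networks, include_global = FALSE) {
  stopifnot(is.data.frame(matrices), length(matrices$matrix) > 0)
  ref <- matrices$matrix[[1]]$roi_labels
  for (m in matrices$matrix) {
    if (!identical(m$roi_labels, ref)) {
      abort("matrices disagree in label ordering; realign_matrix() them explicitly")
    }
  }
  validate_rsns(networks, ref, hemisphere_check = FALSE)
  nets <- networks
  if (include_global) nets <- c(nets, list(global = NULL))
  rows <- purrr::imap(nets, function(members, nm) {
    tibble::tibble(
      subject = matrices$subject,
      timepoint = matrices$timepoint,
      band = matrices$band,
      network = nm,
      mean_pli = vapply(matrices$matrix, mean_pli, numeric(1),
                        roi_subset = members)
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$subject, .data$timepoint, .data$band,
                 .data$network)
}
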