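#' Heatmap of a PLI connectivity matrix
#'
#' @param object A `pli_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pli_matrix
#' @export
autoplot.pli_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi_a, y = .data$roi_b,
                                   fill = .data$pli)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "PLI") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = if (is.null(object$band)) "PLI connectivity" else
                    sprintf("PLI connectivity (%s)", object$band$band)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' Paired T1/T2 network connectivity plot
#'
#' Per-subject paired points and lines of mean network PLI at both
#' timepoints, faceted by band and network — the standard display for a
#' longitudinal connectivity change.
#'
#' @param summaries Tibble from [summarize_rsns()].
#' @param networks Optional subset of network names to show.
#' @return A ggplot.
#' @export
plot_rsn_change <- function(summaries, networks = NULL) {
  df <- summaries
  if (!is.null(networks)) df <- df[df$network %in% networks, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$mean_pli,
                                   group = .data$subject)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 1) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", linewidth = 1, colour = "firebrick") +
    ggplot2::facet_grid(band ~ network) +
    ggplot2::labs(x = NULL, y = "mean network PLI") +
    ggplot2::theme_bw()
}

#' Connectivity-change versus cognitive-change scatter
#'
#' @param report A `stat_report` from [run_full_inference()].
#' @param cognition Tibble with `subject`, `domain`, `delta`.
#' @param band,network,domain Cell to plot.
#' @return A ggplot.
#' @export
plot_connectivity_cognition <- function(report, cognition, band, network,
                                        domain) {
  dp <- report$delta_pli
  dp <- dp[dp$band == band & dp$network == network, ]
  cd <- cognition[cognition$domain == domain, ]
  df <- dplyr::inner_join(dp[, c("subject", "delta_pli")],
                          cd[, c("subject", "delta")], by = "subject")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_pli, y = .data$delta)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "grey40") +
    ggplot2::labs(x = sprintf("%s %s PLI change (T2 - T1)", network, band),
                  y = sprintf("%s delta z-score", domain)) +
    ggplot2::theme_bw()
}
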