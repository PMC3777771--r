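#' Wilcoxon signed-rank test for paired T1/T2 values
#'
#' Zero differences are dropped (Wilcoxon's original rule), tied absolute
#' differences receive average ranks, and the z statistic uses the
#' tie-corrected normal-approximation variance
#' \eqn{n(n+1)(2n+1)/24 - \sum(t^3 - t)/48}. The sign convention follows the
#' usual clinical-software reporting: differences are `t1 - t2`, so a group
#' *increase* at T2 yields a negative z. The two-sided p-value comes from
#' exhaustive enumeration of all sign assignments (via the exact
#' distribution of the positive-rank sum) when `n <= 15` without relying on
#' the approximation, or from the continuity-corrected normal approximation
#' otherwise (the reported z is the plain standardized statistic).
#'
#' @param t1,t2 Equal-length numeric vectors aligned by subject; pairs with
#'   a missing value are dropped.
#' @param method `"auto"` (exact for n <= 15, else approximate), `"exact"`,
#'   or `"approx"`.
#' @return Object of class `wsr_test`: `n` (non-zero pairs), `statistic`
#'   (positive-rank sum of t1 - t2), `z`, `p_value`, `method`.
#' @export
wilcoxon_signed_rank <- function(t1, t2, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  if (length(t1) != length(t2)) abort("t1 and t2 must be aligned by subject")
  keep <- stats::complete.cases(t1, t2)
  d <- t1[keep] - t2[keep]
  if (length(d) < 5) abort("need at least 5 complete pairs")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("all paired differences are zero; test degenerate")
    return(structure(list(n = 0L, statistic = NA_real_, z = 0,
                          p_value = 1, method = "degenerate"),
                     class = "wsr_test"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w - mu) / sqrt(sigma2)
  use_exact <- method == "exact" || (method == "auto" && n <= 15)
  p <- if (use_exact) {
    wsr_exact_p(r, w)
  } else {
    # continuity-corrected approximate p; the reported z stays uncorrected
    2 * pnorm(-max(abs(w - mu) - 0.5, 0) / sqrt(sigma2))
  }
  structure(list(n = n, statistic = w, z = z, p_value = min(p, 1),
                 method = if (use_exact) "exact" else "approx"),
            class = "wsr_test")
}

# Exact two-sided p for the positive-rank sum: distribution of W over all
# 2^n sign assignments of the observed ranks, by convolution on a half-unit
# grid (average ranks can end in .5). p = P(|W - mu| >= |w - mu|).
wsr_exact_p <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  dist <- numeric(total + 1)  # index k+1 <-> doubled rank-sum k
  dist[1] <- 1
  for (rr in r2) {
    shifted <- c(numeric(rr), dist[seq_len(total + 1 - rr)])
    dist <- (dist + shifted) / 2
  }
  mu2 <- total / 2
  dev <- abs(round(2 * w) - mu2)
  sums <- seq(0, total)
  sum(dist[abs(sums - mu2) >= dev - 1e-9])
}

#' @export
print.wsr_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: n = %d, W = %g, z = %.3f, p = %.4g (%s)\n",
              x$n, x$statistic, x$z, x$p_value, x$method))
  invisible(x)
}

#' @method tidy wsr_test
#' @export
tidy.wsr_test <- function(x, ...) {
  tibble::tibble(n = x$n, statistic = x$statistic, z = x$z,
                 p_value = x$p_value, method = x$method)
}

#' Benjamini-Hochberg correction within each frequency band
#'
#' Applies the step-up false-discovery-rate procedure at level `q`
#' separately within each band's family of tests, never pooling across
#' bands. Adds `p_adjusted` and `fdr_significant` columns.
#'
#' @param results Tibble with at least `band` and `p_value` columns.
#' @param q FDR level (default 0.05).
#' @return The input with `p_adjusted` and `fdr_significant` added.
#' @export
fdr_per_band <- function(results, q = 0.05) {
  stopifnot(all(c("band", "p_value") %in% names(results)))
  results |>
    dplyr::group_by(.data$band) |>
    dplyr::mutate(p_adjusted = p.adjust(.data$p_value, method = "BH"),
                  fdr_significant = .data$p_adjusted <= q) |>
    dplyr::ungroup()
}

#' Kendall rank correlation (tau-b)
#'
#' Concordant/discordant pair counts with tie correction in both margins.
#' The two-sided p-value is exact (from the inversion-count distribution of
#' all n! orderings) for tie-free data with n <= 10, otherwise from the
#' normal approximation with the standard tie-corrected variance.
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped pairwise.
#' @param method `"auto"`, `"exact"` or `"approx"`.
#' @return Object of class `tau_test`: `n`, `tau`, `p_value`, `method`.
#'   Constant `x` or `y` gives `tau = NA` with a warning.
#' @export
kendall_tau <- function(x, y, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) abort("need at least 5 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warn("tau undefined for a constant input; reported as missing")
    return(structure(list(n = n, tau = NA_real_, p_value = NA_real_,
                          method = "degenerate"), class = "tau_test"))
  }
  C <- 0L; D <- 0L
  for (i in seq_len(n - 1)) {
    dx <- x[(i + 1):n] - x[i]
    dy <- y[(i + 1):n] - y[i]
    s <- sign(dx) * sign(dy)
    C <- C + sum(s > 0)
    D <- D + sum(s < 0)
  }
  tx <- table(x); ty <- table(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- (C - D) / sqrt((n0 - n1) * (n0 - n2))
  has_ties <- n1 > 0 || n2 > 0
  use_exact <- !has_ties && (method == "exact" ||
                               (method == "auto" && n <= 10))
  if (method == "exact" && has_ties) {
    warn("exact tau p-value unavailable with ties; using the normal approximation")
  }
  p <- if (use_exact) {
    tau_exact_p(n, D)
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    v <- (v0 - vt - vu) / 18 + v1 + v2
    zstat <- (C - D) / sqrt(v)
    2 * pnorm(-abs(zstat))
  }
  structure(list(n = n, tau = tau, p_value = min(p, 1),
                 method = if (use_exact) "exact" else "approx"),
            class = "tau_test")
}

# Exact two-sided p from the Mahonian (inversion-count) distribution: the
# number of discordant pairs of a random tie-free pairing is distributed as
# the inversion count of a uniform permutation of n items.
tau_exact_p <- function(n, d) {
  max_inv <- n * (n - 1) / 2
  counts <- 1
  for (k in 2:n) {
    new <- numeric(length(counts) + k - 1)
    for (s in 0:(k - 1)) {
      idx <- seq_along(counts) + s
      new[idx] <- new[idx] + counts
    }
    counts <- new
  }
  probs <- counts / sum(counts)
  dev <- abs(d - max_inv / 2)
  inv <- seq(0, max_inv)
  sum(probs[abs(inv - max_inv / 2) >= dev - 1e-9])
}

#' @export
print.tau_test <- function(x, ...) {
  cat(sprintf("Kendall tau-b: n = %d, tau = %.3f, p = %.4g (%s)\n",
              x$n, x$tau, x$p_value, x$method))
  invisible(x)
}

#' @method tidy tau_test
#' @export
tidy.tau_test <- function(x, ...) {
  tibble::tibble(n = x$n, tau = x$tau, p_value = x$p_value, method = x$method)
}

#' Full three-stage longitudinal inference
#'
#' The inferential chain for a two-timepoint cohort: (1) global mean PLI
#' T1 vs T2 per band (its own family under FDR); (2) per-network per-band
#' paired tests with Benjamini-Hochberg FDR within each band's family of
#' network tests; (3) post-hoc Kendall tau between each FDR-surviving
#' (band, network) cell's per-subject PLI change and every cognitive
#' domain's delta score, uncorrected (post-hoc reporting). Subjects missing
#' cognition are excluded from stage 3 only.
#'
#' @param summaries Tibble from [summarize_rsns()] with `include_global =
#'   TRUE` if global tests are wanted (`network == "global"` rows feed
#'   stage 1; all other networks feed stage 2).
#' @param cognition Tibble with `subject`, `domain`, `delta` (e.g. a
#'   `meg_cohort$cognition` or [delta_scores()] output).
#' @param q FDR level (default 0.05).
#' @param wilcoxon_method,tau_method Passed to the component tests.
#' @return Object of class `stat_report`: tibbles `global_tests`,
#'   `network_tests`, `correlations`, `delta_pli` (per-subject network PLI
#'   changes), and counts `n_subjects`, `n_cognition`.
#' @export
run_full_inference <- function(summaries, cognition = NULL, q = 0.05,
                               wilcoxon_method = "auto",
                               tau_method = "auto") {
  stopifnot(all(c("subject", "timepoint", "band", "network", "mean_pli")
                %in% names(summaries)))
  if (!all(c("T1", "T2") %in% unique(summaries$timepoint))) {
    abort("summaries must cover both timepoints")
  }
  wide <- summaries |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "mean_pli")
  if (anyNA(wide$T1) || anyNA(wide$T2)) {
    abort("every (subject, band, network) needs both timepoints")
  }
  n_subjects <- length(unique(wide$subject))
  if (n_subjects < 5) abort("need at least 5 complete subjects")
  wide$delta_pli <- wide$T2 - wide$T1

  run_cell <- function(df) {
    t <- wilcoxon_signed_rank(df$T1, df$T2, method = wilcoxon_method)
    tibble::tibble(n = t$n, z = t$z, p_value = t$p_value, method = t$method)
  }
  global <- wide |> dplyr::filter(.data$network == "global")
  # the global per-band tests form one family of their own (not pooled with
  # the network families)
  global_tests <- if (nrow(global) > 0) {
    global |>
      dplyr::group_by(.data$band) |>
      dplyr::group_modify(~ run_cell(.x)) |>
      dplyr::ungroup() |>
      dplyr::mutate(p_adjusted = p.adjust(.data$p_value, method = "BH"),
                    fdr_significant = .data$p_adjusted <= q,
                    network = "global", .after = "band")
  } else {
    tibble::tibble()
  }

  nets <- wide |> dplyr::filter(.data$network != "global")
  network_tests <- nets |>
    dplyr::group_by(.data$band, .data$network) |>
    dplyr::group_modify(~ run_cell(.x)) |>
    dplyr::ungroup() |>
    fdr_per_band(q = q)

  correlations <- tibble::tibble()
  surviving <- network_tests |> dplyr::filter(.data$fdr_significant)
  n_cog <- 0L
  if (!is.null(cognition) && nrow(surviving) > 0) {
    stopifnot(all(c("subject", "domain", "delta") %in% names(cognition)))
    complete_cog <- cognition |>
      dplyr::group_by(.data$subject) |>
      dplyr::filter(!anyNA(.data$delta)) |>
      dplyr::ungroup()
    n_cog <- length(unique(complete_cog$subject))
    rows <- purrr::pmap(surviving[, c("band", "network")], function(band, network) {
      cell <- wide[wide$band == band & wide$network == network, ]
      purrr::map(unique(complete_cog$domain), function(dom) {
        cd <- complete_cog[complete_cog$domain == dom, ]
        merged <- dplyr::inner_join(cell[, c("subject", "delta_pli")],
                                    cd[, c("subject", "delta")],
                                    by = "subject")
        t <- kendall_tau(merged$delta_pli, merged$delta, method = tau_method)
        tibble::tibble(band = band, network = network, domain = dom,
                       n = t$n, tau = t$tau, p_value = t$p_value,
                       method = t$method)
      }) |> dplyr::bind_rows()
    })
    correlations <- dplyr::bind_rows(rows)
  }

  structure(
    list(global_tests = global_tests, network_tests = network_tests,
         correlations = correlations,
         delta_pli = wide[, c("subject", "band", "network", "T1", "T2",
                              "delta_pli")],
         n_subjects = n_subjects, n_cognition = n_cog, q = q),
    class = "stat_report"
  )
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report> %d subjects (%d with cognition)\n",
              x$n_subjects, x$n_cognition))
  if (nrow(x$global_tests)) {
    cat("Global PLI change per band:\n")
    print(as.data.frame(x$global_tests[, c("band", "z", "p_value",
                                           "fdr_significant")]), row.names = FALSE)
  }
  sig <- x$network_tests[x$network_tests$fdr_significant, ]
  cat(sprintf("Network tests: %d, FDR-surviving: %d\n",
              nrow(x$network_tests), nrow(sig)))
  if (nrow(sig)) {
    print(as.data.frame(sig[, c("band", "network", "z", "p_value",
                                "p_adjusted")]), row.names = FALSE)
  }
  if (nrow(x$correlations)) {
    cat("Post-hoc connectivity-cognition correlations:\n")
    print(as.data.frame(x$correlations[, c("band", "network", "domain",
                                           "tau", "p_value")]),
          row.names = FALSE)
  }
  invisible(x)
}

#' Tidy one table of a stat report
#'
#' @param x A `stat_report`.
#' @param which `"network_tests"` (default), `"global_tests"`,
#'   `"correlations"`, or `"delta_pli"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy stat_report
#' @export
tidy.stat_report <- function(x, which = "network_tests", ...) {
  which <- match.arg(which, c("network_tests", "global_tests",
                              "correlations", "delta_pli"))
  tibble::as_tibble(x[[which]])
}

#' One-line summary of a stat report
#' @param x A `stat_report`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance stat_report
#' @export
glance.stat_report <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_cognition = x$n_cognition,
    n_network_tests = nrow(x$network_tests),
    n_fdr_significant = sum(x$network_tests$fdr_significant),
    n_correlations = nrow(x$correlations),
    q = x$q
  )
}
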