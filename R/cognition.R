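#' Default subtest-to-domain map
#'
#' The standard six-subtest battery and the cognitive domains each subtest
#' measures; a subtest can feed several domains. `polarity` is -1 for timed
#' scores where lower raw values mean better performance (they are
#' sign-flipped before standardization) and +1 otherwise.
#'
#' @return Tibble with columns `subtest`, `domain`, `polarity`.
#' @export
default_domain_map <- function() {
  tibble::tribble(
    ~subtest,                      ~domain,                  ~polarity,
    "concept_shifting_test",       "executive_functioning",  -1,
    "concept_shifting_test",       "psychomotor_speed",      -1,
    "categoric_word_fluency",      "executive_functioning",   1,
    "rey_auditory_verbal_learning", "verbal_memory",           1,
    "stroop_color_word",           "attention",              -1,
    "memory_comparison",           "working_memory",         -1,
    "letter_digit_substitution",   "information_processing",  1,
    "letter_digit_substitution",   "psychomotor_speed",       1
  )
}

#' Raw subtest scores to per-domain scores
#'
#' Standardizes every subtest against the T1 group (after applying its
#' polarity flag) and averages the standardized subtest scores within each
#' domain; a subtest mapped to several domains contributes to each. The
#' `overall` composite is the mean of *all* standardized subtest scores.
#'
#' @param raw Tibble with columns `subject`, `timepoint` (`"T1"`/`"T2"`),
#'   `subtest`, `score`.
#' @param map Subtest-to-domain map as in [default_domain_map()].
#' @param include_overall Append an `overall` pseudo-domain (default TRUE).
#' @return Tibble: `subject`, `timepoint`, `domain`, `score` (standardized
#'   domain score).
#' @export
domain_scores <- function(raw, map = default_domain_map(),
                          include_overall = TRUE) {
  stopifnot(all(c("subject", "timepoint", "subtest", "score") %in% names(raw)))
  unmapped <- setdiff(unique(raw$subtest), unique(map$subtest))
  if (length(unmapped) > 0) {
    warn(sprintf("unmapped subtest(s) ignored: %s",
                 paste(unmapped, collapse = ", ")))
    raw <- raw[raw$subtest %in% map$subtest, ]
  }
  missing_sub <- raw |>
    dplyr::distinct(.data$subject, .data$timepoint, .data$subtest) |>
    dplyr::count(.data$subject, .data$timepoint) |>
    dplyr::filter(.data$n < length(unique(map$subtest)))
  if (nrow(missing_sub) > 0) {
    warn(sprintf("%d subject/timepoint record(s) are missing subtests; their domain scores use the available subtests",
                 nrow(missing_sub)))
  }
  polarity <- dplyr::distinct(map, .data$subtest, .data$polarity)
  std <- raw |>
    dplyr::left_join(polarity, by = "subtest") |>
    dplyr::mutate(score = .data$score * .data$polarity) |>
    dplyr::group_by(.data$subtest) |>
    dplyr::mutate(
      m1 = mean(.data$score[.data$timepoint == "T1"]),
      s1 = sd(.data$score[.data$timepoint == "T1"]),
      z = (.data$score - .data$m1) / .data$s1
    ) |>
    dplyr::ungroup()
  if (any(!is.finite(std$z))) {
    abort("zero T1 standard deviation for at least one subtest")
  }
  out <- std |>
    dplyr::left_join(dplyr::select(map, "subtest", "domain"), by = "subtest",
                     relationship = "many-to-many") |>
    dplyr::group_by(.data$subject, .data$timepoint, .data$domain) |>
    dplyr::summarise(score = mean(.data$z), .groups = "drop")
  if (any(is.na(out$score))) abort("a domain ended up with no subtest scores")
  if (include_overall) {
    overall <- std |>
      dplyr::group_by(.data$subject, .data$timepoint) |>
      dplyr::summarise(domain = "overall", score = mean(.data$z),
                       .groups = "drop")
    out <- dplyr::bind_rows(out, overall)
  }
  dplyr::arrange(out, .data$subject, .data$timepoint, .data$domain)
}

#' Anchor domain scores to the T1 group
#'
#' z = (score - T1 group mean) / T1 group SD, per domain, at *both*
#' timepoints; by construction the T1 z-scores have group mean 0 and SD 1,
#' and the baseline statistics are frozen at T1 (recomputing T2 never moves
#' them). The baseline mean/SD table travels as the `"baseline_stats"`
#' attribute.
#'
#' @param scores Tibble with `subject`, `timepoint`, `domain`, `score`.
#' @return The input with a `z` column added and a `baseline_stats`
#'   attribute (tibble `domain`, `mean`, `sd`).
#' @export
zscore_t1_anchored <- function(scores) {
  stopifnot(all(c("subject", "timepoint", "domain", "score") %in% names(scores)))
  base <- scores |>
    dplyr::filter(.data$timepoint == "T1") |>
    dplyr::group_by(.data$domain) |>
    dplyr::summarise(mean = mean(.data$score), sd = sd(.data$score),
                     n = dplyr::n(), .groups = "drop")
  if (any(base$n < 2)) abort("need at least two T1 subjects per domain")
  degenerate <- base$domain[base$sd == 0]
  if (length(degenerate) > 0) {
    abort(sprintf("zero T1 SD in domain(s): %s",
                  paste(degenerate, collapse = ", ")))
  }
  out <- scores |>
    dplyr::left_join(dplyr::select(base, "domain", "mean", "sd"), by = "domain") |>
    dplyr::mutate(z = (.data$score - .data$mean) / .data$sd) |>
    dplyr::select(-"mean", -"sd")
  attr(out, "baseline_stats") <- dplyr::select(base, "domain", "mean", "sd")
  out
}

#' Baseline statistics frozen into a z-scored table
#' @param x Output of [zscore_t1_anchored()].
#' @return Tibble `domain`, `mean`, `sd`.
#' @export
baseline_stats <- function(x) attr(x, "baseline_stats")

#' Longitudinal delta scores
#'
#' delta = z(T2) - z(T1) per subject and domain; positive values mean better
#' performance at follow-up. Subjects lacking either timepoint get an `NA`
#' delta and are reported, never imputed.
#'
#' @param z_table Tibble with `subject`, `timepoint`, `domain`, `z` (as from
#'   [zscore_t1_anchored()]).
#' @return Tibble: `subject`, `domain`, `z_t1`, `z_t2`, `delta`.
#' @export
delta_scores <- function(z_table) {
  stopifnot(all(c("subject", "timepoint", "domain", "z") %in% names(z_table)))
  wide <- z_table |>
    dplyr::select("subject", "timepoint", "domain", "z") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "z",
                       names_prefix = "z_") |>
    dplyr::rename_with(tolower)
  if (!"z_t2" %in% names(wide)) wide$z_t2 <- NA_real_
  if (!"z_t1" %in% names(wide)) wide$z_t1 <- NA_real_
  wide$delta <- wide$z_t2 - wide$z_t1
  incomplete <- unique(wide$subject[is.na(wide$delta)])
  if (length(incomplete) > 0) {
    rlang::inform(sprintf("subject(s) without both timepoints carried as NA: %s",
                          paste(incomplete, collapse = ", ")))
  }
  dplyr::arrange(wide[, c("subject", "domain", "z_t1", "z_t2", "delta")],
                 .data$subject, .data$domain)
}

#' Packaged ten-patient cognitive delta-score table
#'
#' Delta scores (T2 z minus T1 z, positive = improvement) per cognitive
#' domain for a ten-patient longitudinal glioma-surgery cohort; two patients
#' lack follow-up assessment and carry `NA` rows. Useful as a realistic
#' cognitive-change input for the statistical layer.
#'
#' @param long Return one row per subject x domain (default) instead of the
#'   wide on-disk layout.
#' @return A tibble.
#' @export
cognitive_deltas_fixture <- function(long = TRUE) {
  path <- system.file("extdata", "cognitive_deltas.csv", package = "megrsn")
  wide <- tibble::as_tibble(read.table(path, header = TRUE, sep = ","))
  if (!long) return(wide)
  tidyr::pivot_longer(wide, -"subject", names_to = "domain",
                      values_to = "delta")
}
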