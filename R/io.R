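#' Write a cohort to delimited-text containers
#'
#' One tab-separated channels x samples array per subject/timepoint (labels
#' in the first column), a `manifest.tsv` (subject, timepoint, file, rate,
#' seed), and a `cognition.tsv` delta-score table.
#'
#' @param cohort A `meg_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "meg_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  recs <- cohort$recordings
  files <- character(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    ts <- recs$ts[[i]]
    files[i] <- sprintf("sub%02d_%s.tsv", recs$subject[i], recs$timepoint[i])
    df <- data.frame(label = ts$labels, roi = ts$roi, ts$data,
                     check.names = FALSE)
    write.table(df, file.path(dir, files[i]), sep = "\t", row.names = FALSE,
                quote = FALSE)
  }
  manifest <- data.frame(subject = recs$subject, timepoint = recs$timepoint,
                         file = files,
                         rate = vapply(recs$ts, function(t) t$rate, numeric(1)),
                         seed = cohort$spec$seed)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(as.data.frame(cohort$cognition), file.path(dir, "cognition.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.tsv`.
#' @return A list with `recordings` (tibble: subject, timepoint, ts) and
#'   `cognition` (tibble), mirroring the readable parts of a `meg_cohort`.
#' @export
read_cohort <- function(dir) {
  mf_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf_path)) abort(sprintf("no manifest.tsv under %s", dir))
  manifest <- read.table(mf_path, header = TRUE, sep = "\t")
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    df <- read.table(file.path(dir, manifest$file[i]), header = TRUE,
                     sep = "\t", check.names = FALSE)
    ts <- roi_ts(as.matrix(df[, -(1:2)]), df$label, manifest$rate[i],
                 roi = df$roi)
    tibble::tibble(subject = manifest$subject[i],
                   timepoint = manifest$timepoint[i], ts = list(ts))
  })
  cog_path <- file.path(dir, "cognition.tsv")
  cognition <- if (file.exists(cog_path)) {
    tibble::as_tibble(read.table(cog_path, header = TRUE, sep = "\t"))
  } else NULL
  list(recordings = dplyr::bind_rows(recs), cognition = cognition)
}

#' Write a connectivity matrix as square delimited text
#'
#' Square tab-separated table with ROI labels as header row and first
#' column.
#'
#' @param matrix A `pli_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pli_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "pli_matrix"))
  df <- data.frame(roi = matrix$roi_labels, matrix$values, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a connectivity matrix written by [write_pli_matrix()]
#'
#' @param path File path.
#' @param band Optional band tag to attach.
#' @return A `pli_matrix`.
#' @export
read_pli_matrix <- function(path, band = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  labels <- df$roi
  vals <- as.matrix(df[, -1])
  dimnames(vals) <- list(labels, labels)
  structure(list(values = vals, roi_labels = labels,
                 band = if (is.null(band)) NULL else get_band(band),
                 n_epochs_averaged = NA_integer_),
            class = "pli_matrix")
}
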