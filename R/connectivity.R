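## Functional connectivity: optional band-pass filtering of ROI series
## and region-by-region Pearson correlation.

#' Zero-phase Butterworth band-pass filter for ROI time series
#'
#' Applies an order-2 Butterworth band-pass forward and backward
#' (zero phase) to each region's series. The default band 0.01--0.08 Hz
#' is the conventional resting-state BOLD band.
#'
#' @param ts an `roi_timeseries`.
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1/(2 tr_seconds)` (the Nyquist frequency).
#' @param order Butterworth order (per pass).
#' @return a filtered `roi_timeseries` of identical shape.
#' @export
bandpass_filter <- function(ts, low_hz = 0.01, high_hz = 0.08, order = 2L) {
  stopifnot(inherits(ts, "roi_timeseries"))
  nyquist <- 1 / (2 * ts$tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz))
    stop_invalid("band edges must satisfy 0 < low_hz < high_hz")
  if (high_hz >= nyquist)
    stop_invalid("high_hz (%.4g Hz) must be below the Nyquist frequency (%.4g Hz)",
                 high_hz, nyquist)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
  # forward-backward filtering needs settled edges: demean, then filter
  # an odd-symmetric edge extension and strip it afterwards
  pad <- 3 * max(length(bf$a), length(bf$b))
  if (nrow(ts$values) <= pad)
    stop_invalid("series too short (%d timepoints) for zero-phase filtering; need > %d",
                 nrow(ts$values), pad)
  out <- ts
  out$values <- apply(ts$values, 2, function(col) {
    col <- col - mean(col)
    n <- length(col)
    ext <- c(2 * col[1] - col[(pad + 1):2],
             col,
             2 * col[n] - col[(n - 1):(n - pad)])
    signal::filtfilt(bf, ext)[(pad + 1):(pad + n)]
  })
  colnames(out$values) <- colnames(ts$values)
  out
}

#' Compute a subject's functional-connectivity matrix
#'
#' Entry (i, j), i != j, is the Pearson correlation between the series of
#' regions i and j; the diagonal (self-coupling) is set to 0, the
#' connectome convention used downstream when the matrix becomes the
#' system adjacency.
#'
#' @param ts an `roi_timeseries` with at least 3 timepoints and nonzero
#'   variance in every region.
#' @param absolute if `TRUE`, take absolute values of the correlations
#'   (sign-discarding mode); default keeps signed weights.
#' @return a `connectivity_matrix`: list with `values`, `region_labels`,
#'   `subject_id`, `group_label`.
#' @export
compute_fc <- function(ts, absolute = FALSE) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (nrow(ts$values) < 3)
    stop_invalid("need at least 3 timepoints to estimate correlations")
  sds <- apply(ts$values, 2, stats::sd)
  if (any(sds == 0))
    stop_invalid("zero-variance region(s): %s",
                 paste(ts$region_labels[sds == 0], collapse = ", "))
  r <- stats::cor(ts$values)
  if (absolute) r <- abs(r)
  r <- (r + t(r)) / 2   # remove any floating-point asymmetry
  diag(r) <- 0
  structure(list(values = r,
                 region_labels = ts$region_labels,
                 subject_id = ts$subject_id,
                 group_label = ts$group_label),
            class = "connectivity_matrix")
}

#' Functional connectivity for every subject in a cohort
#'
#' Accepts either an in-memory `roi_cohort` or the path to a cohort
#' manifest TSV (columns `subject_id`, `group_label`, `path`) written by
#' [write_cohort()]. Order is preserved.
#'
#' @param cohort an `roi_cohort`, a list of `roi_timeseries`, or a
#'   manifest path.
#' @param filter_band optional numeric `c(low_hz, high_hz)`; when given,
#'   [bandpass_filter()] is applied before the correlation.
#' @param absolute passed to [compute_fc()].
#' @return list of `connectivity_matrix`, one per subject.
#' @export
fc_for_cohort <- function(cohort, filter_band = NULL, absolute = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort_manifest(cohort)
  lapply(cohort, function(ts) {
    if (!is.null(filter_band))
      ts <- bandpass_filter(ts, filter_band[1], filter_band[2])
    compute_fc(ts, absolute = absolute)
  })
}

read_cohort_manifest <- function(path) {
  manifest <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group_label", "path")
  if (!all(need %in% names(manifest)))
    stop_invalid("manifest must have columns %s", paste(need, collapse = ", "))
  lapply(seq_len(nrow(manifest)), function(i) {
    f <- manifest$path[i]
    if (!file.exists(f))
      stop_invalid("time-series file for subject '%s' not readable: %s",
                   manifest$subject_id[i], f)
    vals <- as.matrix(utils::read.delim(f, check.names = FALSE))
    structure(list(subject_id = manifest$subject_id[i],
                   group_label = as.integer(manifest$group_label[i]),
                   values = vals,
                   tr_seconds = attr(manifest, "tr_seconds", exact = TRUE) %||% 0.5,
                   region_labels = colnames(vals)),
              class = "roi_timeseries")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write per-subject connectivity matrices as labelled TSV files
#' @param fcs list of `connectivity_matrix`.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_fc_matrices <- function(fcs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(fcs, function(fc) {
    f <- file.path(dir, paste0(fc$subject_id, "_fc.tsv"))
    m <- fc$values
    dimnames(m) <- list(fc$region_labels, fc$region_labels)
    utils::write.table(m, f, sep = "\t", quote = FALSE, col.names = NA)
    f
  }, character(1))
  invisible(paths)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("Functional connectivity: subject %s (group %d), %d regions, FC range [%.3f, %.3f]\n",
              x$subject_id, x$group_label, nrow(x$values), min(off), max(off)))
  invisible(x)
}
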