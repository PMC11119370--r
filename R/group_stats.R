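## Region-wise two-group comparison of controllability profiles.

#' Pooled-variance two-sample t-test
#'
#' Student's t with pooled variance and `n_a + n_b - 2` degrees of
#' freedom, two-sided p from the t distribution. Thin wrapper over
#' [stats::t.test()]; a Welch variant is available via `var_equal`.
#'
#' @param x,y numeric vectors (each length >= 2 with finite variance).
#' @param var_equal pooled-variance Student's t when `TRUE` (default),
#'   Welch otherwise.
#' @return list with `t_value` and `p_t`.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2)
    stop_invalid("each group needs at least 2 values")
  if (!all(is.finite(c(x, y))))
    stop_invalid("non-finite values in input")
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t_value = unname(ht$statistic), p_t = ht$p.value)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midrank tie handling; two-sided p by the normal
#' approximation with tie and continuity correction (via
#' [stats::wilcox.test()]). The returned U counts pairs where an x
#' observation exceeds a y observation (ties count 1/2).
#'
#' @param x,y numeric vectors (each non-empty).
#' @param exact force the exact distribution (small samples, no ties).
#' @return list with `u_value` and `p_u`.
#' @export
mann_whitney <- function(x, y, exact = FALSE) {
  if (length(x) < 1 || length(y) < 1)
    stop_invalid("each group needs at least 1 value")
  ht <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  list(u_value = unname(ht$statistic), p_u = ht$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (`m * p / rank`, monotone-enforced, clipped
#' at 1), order-preserving. Validates the input range and delegates to
#' [stats::p.adjust()].
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_invalid("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Region-wise comparison of two groups of controllability profiles
#'
#' One row per region: group means, their difference (group A minus
#' group B, the healthy-minus-patient convention), pooled t-test,
#' Mann-Whitney U, and BH-FDR-adjusted t-test p-values across regions.
#'
#' @param profiles a `ctrl_profile_set` (see [profiles_for_cohort()]).
#' @param alpha significance level stored on the table (default 0.05).
#' @param var_equal passed to [two_sample_t()].
#' @param region_ids optional atlas indices (default `1:n_regions`).
#' @return a `comparison_table`: data.frame with columns `region_id`,
#'   `region_name`, `mean_a`, `mean_b`, `diff`, `t_value`, `p_t`,
#'   `u_value`, `p_u`, `p_fdr`, plus attributes `n_a`, `n_b`, `alpha`.
#' @export
compare_groups <- function(profiles, alpha = 0.05, var_equal = TRUE,
                           region_ids = NULL) {
  stopifnot(inherits(profiles, "ctrl_profile_set"))
  g <- profiles$group_label
  if (!all(g %in% c(0L, 1L)))
    stop_invalid("group labels must be 0 or 1")
  a <- profiles$values[g == 0L, , drop = FALSE]
  b <- profiles$values[g == 1L, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0)
    stop_invalid("both groups must be non-empty")
  n_regions <- ncol(profiles$values)
  region_ids <- region_ids %||% seq_len(n_regions)
  rows <- lapply(seq_len(n_regions), function(j) {
    tt <- two_sample_t(a[, j], b[, j], var_equal = var_equal)
    mw <- mann_whitney(a[, j], b[, j])
    data.frame(region_id = region_ids[j],
               region_name = profiles$region_labels[j],
               mean_a = mean(a[, j]), mean_b = mean(b[, j]),
               diff = mean(a[, j]) - mean(b[, j]),
               t_value = tt$t_value, p_t = tt$p_t,
               u_value = mw$u_value, p_u = mw$p_u,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_fdr <- bh_fdr(tab$p_t)
  structure(tab, class = c("comparison_table", "data.frame"),
            n_a = nrow(a), n_b = nrow(b), alpha = alpha)
}

#' Top-k regions by group difference
#'
#' `direction = "decreased-in-B"` ranks the most positive differences
#' (group A above group B) in decreasing order; `"elevated-in-B"` the
#' most negative differences in increasing order. Ties break by
#' ascending `region_id`.
#'
#' @param table a `comparison_table`.
#' @param k number of regions (1..n).
#' @param direction `"decreased-in-B"` or `"elevated-in-B"`.
#' @return character vector of region names, length `k`.
#' @export
top_k <- function(table, k, direction = c("decreased-in-B", "elevated-in-B")) {
  stopifnot(inherits(table, "comparison_table"))
  direction <- match.arg(direction)
  k <- check_count(k, "k")
  if (k > nrow(table)) stop_invalid("k exceeds the number of regions")
  ord <- if (direction == "decreased-in-B") {
    order(-table$diff, table$region_id)
  } else {
    order(table$diff, table$region_id)
  }
  table$region_name[ord[seq_len(k)]]
}

#' Rows of a comparison table significant at a level
#' @param table a `comparison_table`.
#' @param alpha level (default the table's own).
#' @param use_fdr test `p_fdr` instead of raw `p_t`.
#' @return the significant subset, as a data.frame.
#' @export
significant_regions <- function(table, alpha = attr(table, "alpha"),
                                use_fdr = FALSE) {
  p <- if (use_fdr) table$p_fdr else table$p_t
  as.data.frame(table)[p < alpha, , drop = FALSE]
}

#' Write a comparison table as TSV
#'
#' Column layout mirrors the biomarker-table convention: ID, Name, group
#' means, difference, raw p, t, then U, its p and the FDR-adjusted p.
#'
#' @param table a `comparison_table`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_comparison <- function(table, path) {
  out <- data.frame(ID = table$region_id, Name = table$region_name,
                    Ave_control_HC = table$mean_a,
                    Ave_control_MDD = table$mean_b,
                    `HC-MDD` = table$diff, p_t = table$p_t,
                    T = table$t_value, U = table$u_value,
                    p_u = table$p_u, p_FDR = table$p_fdr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.comparison_table <- function(x, ...) {
  alpha <- attr(x, "alpha")
  cat(sprintf("Region-wise group comparison: %d regions, n = %d vs %d, alpha = %g\n",
              nrow(x), attr(x, "n_a"), attr(x, "n_b"), alpha))
  sig <- x$p_t < alpha
  cat(sprintf("  %d region(s) with p_t < alpha; %d surviving FDR\n",
              sum(sig), sum(x$p_fdr < alpha)))
  if (any(sig)) {
    show <- as.data.frame(x)[sig, c("region_id", "region_name", "mean_a",
                                    "mean_b", "diff", "t_value", "p_t", "p_fdr")]
    print(format(show, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.comparison_table <- function(object, ...) print(object, ...)
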