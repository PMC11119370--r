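## Biomarker evaluation: feature selection from the group comparison,
## stratified k-fold cross-validation of the MLP, ROC/AUC and confusion
## matrices.

#' Build the classifier feature matrix from significant regions
#'
#' Columns are the regions with `p_t < alpha` in the comparison table
#' (or an explicit `regions` override), ordered by atlas `region_id`;
#' rows are the cohort's subjects in order.
#'
#' @param profiles a `ctrl_profile_set`.
#' @param comparison a `comparison_table` computed on the same cohort
#'   (ignored when `regions` is given).
#' @param alpha selection level on the raw t-test p-values.
#' @param regions optional explicit vector of atlas region ids,
#'   bypassing the p-value filter.
#' @return a `feature_matrix`: list with `x` (subjects x features),
#'   `feature_names`, `region_ids`, `y` (0/1 labels).
#' @export
select_features <- function(profiles, comparison = NULL, alpha = 0.05,
                            regions = NULL) {
  stopifnot(inherits(profiles, "ctrl_profile_set"))
  if (is.null(regions)) {
    stopifnot(inherits(comparison, "comparison_table"))
    keep <- comparison$region_id[comparison$p_t < alpha]
    if (length(keep) == 0)
      stop_invalid(paste("no region passes p_t < %g; pass an explicit",
                         "'regions' list to override"), alpha)
  } else {
    keep <- as.integer(regions)
    if (any(keep < 1) || any(keep > ncol(profiles$values)))
      stop_invalid("region ids out of range")
  }
  keep <- sort(unique(keep))
  structure(list(x = profiles$values[, keep, drop = FALSE],
                 feature_names = profiles$region_labels[keep],
                 region_ids = keep,
                 y = profiles$group_label),
            class = "feature_matrix")
}

#' Stratified fold assignment
#'
#' Each class is shuffled and dealt round-robin over `k` folds, so every
#' fold's class proportions are within one subject of the global ratio.
#'
#' @param labels binary label vector.
#' @param k number of folds (>= 2); every class must have >= k members.
#' @param seed integer seed.
#' @return integer vector of fold indices in `1..k`, one per subject.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  k <- check_count(k, "k", min = 2)
  labels <- as.integer(labels)
  tab <- table(labels)
  if (any(tab < k))
    stop_invalid("every class needs at least k = %d members (smallest has %d)",
                 k, min(tab))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in as.integer(names(tab))) {
    idx <- which(labels == cl)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' ROC curve and AUC
#'
#' Sweeps thresholds over the distinct scores (ties grouped), yielding a
#' staircase from (0, 0) to (1, 1); AUC by the trapezoidal rule, which
#' equals the Mann-Whitney concordance probability.
#'
#' @param scores numeric scores, larger = more positive-like.
#' @param labels binary labels (0/1), both classes present.
#' @return list with `roc_points` (data.frame of `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop_invalid("both classes must be present to compute a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # cumulative counts at each distinct-score cut
  last_of_tie <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y == 1)[last_of_tie]
  fp <- cumsum(y == 0)[last_of_tie]
  tpr <- c(0, tp / n1); fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

confusion_counts <- function(pred, truth) {
  c(tp = sum(pred == 1 & truth == 1), tn = sum(pred == 0 & truth == 0),
    fp = sum(pred == 1 & truth == 0), fn = sum(pred == 0 & truth == 1))
}

#' Stratified k-fold cross-validation of the MLP biomarker classifier
#'
#' Trains on k-1 folds and scores the held-out fold, thresholding
#' probabilities at 0.5 for the confusion matrix. Per-fold seeds (and
#' the fold assignment itself) derive from the master `seed`.
#'
#' @param features a `feature_matrix` from [select_features()].
#' @param arch an [mlp_architecture()].
#' @param k number of folds (default 10).
#' @param seed master seed.
#' @param threshold decision threshold on P(y = 1 | x).
#' @return a `cv_report`: list with `fold_results` (per-fold counts,
#'   rates, ROC points and AUC), `pooled_confusion` (2 x 2, true label x
#'   predicted label, classes 0 then 1), `overall_accuracy` (pooled),
#'   `fold_mean_accuracy`, `class_rates` (per-class correct rates),
#'   `auc_mean`, `auc_sd`, `fold_assignment`.
#' @export
cross_validate <- function(features, arch = mlp_architecture(), k = 10L,
                           seed = 1L, threshold = 0.5) {
  stopifnot(inherits(features, "feature_matrix"))
  y <- features$y
  fold <- stratified_folds(y, k = k, seed = mix_seed(seed, 1))
  fold_results <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold == f
    model <- train_mlp(features$x[!test, , drop = FALSE], y[!test],
                       arch = arch, seed = mix_seed(seed, 2, f))
    p <- predict(model, features$x[test, , drop = FALSE])
    pred <- as.integer(p >= threshold)
    cm <- confusion_counts(pred, y[test])
    roc <- roc_auc(p, y[test])
    fold_results[[f]] <- list(
      fold_index = f,
      tp = cm[["tp"]], tn = cm[["tn"]], fp = cm[["fp"]], fn = cm[["fn"]],
      tpr = if (cm[["tp"]] + cm[["fn"]] > 0) cm[["tp"]] / (cm[["tp"]] + cm[["fn"]]) else NA_real_,
      fpr = if (cm[["fp"]] + cm[["tn"]] > 0) cm[["fp"]] / (cm[["fp"]] + cm[["tn"]]) else NA_real_,
      specificity = if (cm[["fp"]] + cm[["tn"]] > 0) cm[["tn"]] / (cm[["fp"]] + cm[["tn"]]) else NA_real_,
      accuracy = (cm[["tp"]] + cm[["tn"]]) / sum(cm),
      roc_points = roc$roc_points,
      auc = roc$auc)
  }
  pooled <- Reduce(`+`, lapply(fold_results, function(fr)
    matrix(c(fr$tn, fr$fp, fr$fn, fr$tp), 2, 2, byrow = TRUE,
           dimnames = list(true = c("0", "1"), predicted = c("0", "1")))))
  aucs <- vapply(fold_results, `[[`, numeric(1), "auc")
  structure(list(fold_results = fold_results,
                 pooled_confusion = pooled,
                 overall_accuracy = sum(diag(pooled)) / sum(pooled),
                 fold_mean_accuracy = mean(vapply(fold_results, `[[`,
                                                  numeric(1), "accuracy")),
                 class_rates = diag(pooled) / rowSums(pooled),
                 auc_mean = mean(aucs), auc_sd = stats::sd(aucs),
                 fold_assignment = fold,
                 k = k, seed = seed, threshold = threshold),
            class = "cv_report")
}

#' Write a CV report as JSON (plus optionally the confusion matrix TSV)
#' @param report a `cv_report`.
#' @param path output JSON path.
#' @param confusion_tsv optional TSV path for the pooled confusion matrix.
#' @return invisibly, `path`.
#' @export
write_cv_report <- function(report, path, confusion_tsv = NULL) {
  payload <- list(
    k = report$k,
    overall_accuracy = report$overall_accuracy,
    fold_mean_accuracy = report$fold_mean_accuracy,
    class_rates = as.list(stats::setNames(report$class_rates, c("hc", "mdd"))),
    auc_mean = report$auc_mean, auc_sd = report$auc_sd,
    pooled_confusion = report$pooled_confusion,
    folds = lapply(report$fold_results, function(fr)
      fr[c("fold_index", "tp", "tn", "fp", "fn", "tpr", "fpr",
           "specificity", "accuracy", "auc", "roc_points")]))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(confusion_tsv))
    utils::write.table(report$pooled_confusion, confusion_tsv, sep = "\t",
                       quote = FALSE, col.names = NA)
  invisible(path)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold stratified CV: pooled accuracy %.3f (fold mean %.3f), AUC %.3f +/- %.3f\n",
              x$k, x$overall_accuracy, x$fold_mean_accuracy, x$auc_mean, x$auc_sd))
  cat(sprintf("  class-0 correct rate %.3f, class-1 correct rate %.3f\n",
              x$class_rates[1], x$class_rates[2]))
  cat("Pooled confusion matrix (rows = true, cols = predicted):\n")
  print(x$pooled_confusion)
  invisible(x)
}

#' Plot the per-fold ROC curves of a CV report
#' @param x a `cv_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cv_report <- function(x, ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "red",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC per fold (mean AUC %.3f)", x$auc_mean), ...)
  for (fr in x$fold_results)
    graphics::lines(fr$roc_points$fpr, fr$roc_points$tpr,
                    col = grDevices::adjustcolor("steelblue", 0.7))
  invisible(x)
}
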