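## End-to-end pipeline: simulate (or ingest) -> connectivity ->
## controllability -> group comparison -> classifier evaluation, with
## plain-text artifacts and a machine-readable run report.

#' Assemble and validate a pipeline run configuration
#'
#' @param cohort a [cohort_config()] for synthetic data, or the path to
#'   a real-data manifest TSV (see [ingest_real_manifest()]).
#' @param filter_enabled apply the band-pass before FC (default off for
#'   synthetic cohorts, whose spectra are already controlled).
#' @param filter_band numeric `c(low_hz, high_hz)` (default 0.01--0.08).
#' @param normalization_c offset in [stabilize_adjacency()].
#' @param alpha significance level for the group comparison.
#' @param var_equal pooled (`TRUE`) vs Welch t-test.
#' @param arch an [mlp_architecture()].
#' @param k_folds CV folds.
#' @param output_dir artifact directory.
#' @param master_seed drives every stage's randomness.
#' @return an object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       filter_enabled = FALSE,
                       filter_band = c(0.01, 0.08),
                       normalization_c = 1,
                       alpha = 0.05, var_equal = TRUE,
                       arch = mlp_architecture(),
                       k_folds = 10L,
                       output_dir = tempfile("brainctrl_run_"),
                       master_seed = 1L) {
  if (!inherits(cohort, "cohort_config") && !is.character(cohort))
    stop_invalid("'cohort' must be a cohort_config or a manifest path")
  stopifnot(inherits(arch, "mlp_architecture"))
  structure(list(cohort = cohort,
                 filter_enabled = isTRUE(filter_enabled),
                 filter_band = as.numeric(filter_band),
                 normalization_c = normalization_c,
                 alpha = alpha, var_equal = isTRUE(var_equal),
                 arch = arch,
                 k_folds = check_count(k_folds, "k_folds", min = 2),
                 output_dir = output_dir,
                 master_seed = check_count(master_seed, "master_seed", min = 0)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys with dotted sections (`cohort.*`, `filter.*`,
#' `controllability.c`, `stats.*`, `classifier.*`, `output_dir`,
#' `master_seed`) mapping one-to-one onto [run_config()] and its
#' sub-configs; omitted keys keep their defaults. A documented defaults
#' file ships at `system.file("extdata", "default_config.yaml",
#' package = "brainctrl")`.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pick <- function(prefix) {
    keys <- grep(paste0("^", prefix, "\\."), names(raw), value = TRUE)
    stats::setNames(raw[keys], sub(paste0("^", prefix, "\\."), "", keys))
  }
  cohort_args <- pick("cohort")
  cohort <- if (length(cohort_args) == 1 && !is.null(cohort_args$manifest)) {
    cohort_args$manifest
  } else {
    do.call(cohort_config, cohort_args)
  }
  arch <- do.call(mlp_architecture, pick("classifier_arch"))
  stats_args <- pick("stats")
  cls_args <- pick("classifier")
  filt_args <- pick("filter")
  ctrl_args <- pick("controllability")
  run_config(cohort = cohort,
             filter_enabled = filt_args$enabled %||% FALSE,
             filter_band = c(filt_args$low_hz %||% 0.01,
                             filt_args$high_hz %||% 0.08),
             normalization_c = ctrl_args$c %||% 1,
             alpha = stats_args$alpha %||% 0.05,
             var_equal = stats_args$var_equal %||% TRUE,
             arch = arch,
             k_folds = cls_args$k_folds %||% 10L,
             output_dir = raw$output_dir %||% tempfile("brainctrl_run_"),
             master_seed = raw$master_seed %||% 1L)
}

#' Serialize a run configuration to the flat YAML layout
#' @param config a `run_config`.
#' @param path output YAML file.
#' @return invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  cc <- config$cohort
  cohort_keys <- if (is.character(cc)) {
    list(cohort.manifest = cc)
  } else {
    stats::setNames(unclass(cc), paste0("cohort.", names(unclass(cc))))
  }
  arch_keys <- stats::setNames(unclass(config$arch),
                               paste0("classifier_arch.", names(unclass(config$arch))))
  out <- c(cohort_keys, arch_keys,
           list(filter.enabled = config$filter_enabled,
                filter.low_hz = config$filter_band[1],
                filter.high_hz = config$filter_band[2],
                controllability.c = config$normalization_c,
                stats.alpha = config$alpha,
                stats.var_equal = config$var_equal,
                classifier.k_folds = config$k_folds,
                output_dir = config$output_dir,
                master_seed = config$master_seed))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Ingest a real-data manifest
#'
#' Reads a TSV with columns `subject_id`, `group_label`, `path`. Files
#' may be either ROI time series (timepoints x regions, header row) or
#' precomputed square connectivity matrices (labelled rows and columns);
#' a manifest mixing both kinds is rejected, as are duplicate subject
#' ids, labels outside {0, 1}, and inconsistent region counts.
#'
#' @param path manifest TSV.
#' @return a list of `roi_timeseries`, or of `connectivity_matrix` when
#'   the files are square labelled matrices.
#' @export
ingest_real_manifest <- function(path) {
  manifest <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group_label", "path")
  if (!all(need %in% names(manifest)))
    stop_invalid("manifest must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(manifest$subject_id))
    stop_invalid("duplicate subject_id in manifest: %s",
                 manifest$subject_id[duplicated(manifest$subject_id)][1])
  if (!all(manifest$group_label %in% c(0, 1)))
    stop_invalid("group_label must be 0 or 1")
  entries <- lapply(seq_len(nrow(manifest)), function(i) {
    f <- manifest$path[i]
    if (!file.exists(f))
      stop_invalid("file for subject '%s' is missing: %s",
                   manifest$subject_id[i], f)
    df <- utils::read.delim(f, check.names = FALSE)
    # a square matrix file carries region labels as its first column
    is_matrix <- !is.na(suppressWarnings(ncol(df))) &&
      is.character(df[[1]]) && ncol(df) == nrow(df) + 1
    if (is_matrix) {
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- df[[1]]
      if (nrow(m) != ncol(m))
        stop_invalid("matrix in '%s' is %d x %d, not square", f, nrow(m), ncol(m))
      structure(list(values = m, region_labels = colnames(m),
                     subject_id = manifest$subject_id[i],
                     group_label = as.integer(manifest$group_label[i])),
                class = "connectivity_matrix")
    } else {
      m <- as.matrix(df)
      structure(list(subject_id = manifest$subject_id[i],
                     group_label = as.integer(manifest$group_label[i]),
                     values = m, tr_seconds = 0.5,
                     region_labels = colnames(m)),
                class = "roi_timeseries")
    }
  })
  kinds <- vapply(entries, function(e) class(e)[1], character(1))
  if (length(unique(kinds)) > 1)
    stop_invalid("manifest mixes time-series and matrix files")
  n_regions <- vapply(entries, function(e) length(e$region_labels), integer(1))
  if (length(unique(n_regions)) > 1)
    stop_invalid("inconsistent region counts across subjects (file: %s)",
                 manifest$path[which(n_regions != n_regions[1])[1]])
  entries
}

#' Run the full pipeline
#'
#' simulate (or ingest) -> band-pass/FC -> stabilization and average
#' controllability -> region-wise comparison -> feature selection and
#' stratified CV of the MLP. All artifacts are written as TSV/JSON under
#' `config$output_dir`; rerunning with the same config reproduces them
#' byte-for-byte (timings aside).
#'
#' @param config a [run_config()].
#' @param verbose print stage progress to stderr.
#' @return a `run_report`: list of stage artifact paths with checksums,
#'   timings, the config echo and headline summary numbers.
#' @export
run_all <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list(); timings <- c()
  say <- function(...) if (verbose) message(sprintf(...))
  tic <- function() proc.time()[["elapsed"]]
  fail_marker <- file.path(config$output_dir, "FAILED")
  run_stage <- function(name, fn) {
    say("stage %s ...", name)
    t0 <- tic()
    out <- tryCatch(fn(), error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 fail_marker)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- tic() - t0
    out
  }

  cohort <- run_stage("simulate", function() {
    if (is.character(config$cohort)) {
      ingest_real_manifest(config$cohort)
    } else {
      cc <- config$cohort
      cc$seed <- mix_seed(config$master_seed, 11)
      generate_cohort(cc)
    }
  })

  fcs <- run_stage("fc", function() {
    if (inherits(cohort[[1]], "connectivity_matrix")) return(cohort)
    fc_for_cohort(cohort,
                  filter_band = if (config$filter_enabled) config$filter_band)
  })

  profiles <- run_stage("control", function()
    profiles_for_cohort(fcs, c = config$normalization_c))
  profile_path <- file.path(config$output_dir, "profiles.tsv")
  write_profiles(profiles, profile_path)

  comparison <- run_stage("compare", function()
    compare_groups(profiles, alpha = config$alpha,
                   var_equal = config$var_equal))
  comparison_path <- file.path(config$output_dir, "comparison.tsv")
  write_comparison(comparison, comparison_path)
  sig <- significant_regions(comparison)
  sig_path <- file.path(config$output_dir, "significant_regions.tsv")
  utils::write.table(sig, sig_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  report_cv <- run_stage("classify", function() {
    features <- select_features(profiles, comparison, alpha = config$alpha)
    cross_validate(features, arch = config$arch, k = config$k_folds,
                   seed = mix_seed(config$master_seed, 12))
  })
  cv_path <- file.path(config$output_dir, "cv_report.json")
  write_cv_report(report_cv, cv_path,
                  confusion_tsv = file.path(config$output_dir,
                                            "confusion_matrix.tsv"))

  artifacts <- c(profiles = profile_path, comparison = comparison_path,
                 significant = sig_path, cv = cv_path)
  report <- structure(list(
    artifacts = data.frame(stage = names(artifacts), path = unname(artifacts),
                           md5 = unname(tools::md5sum(artifacts)),
                           stringsAsFactors = FALSE),
    timings = unlist(timings),
    config = config,
    versions = list(r = as.character(getRversion()),
                    brainctrl = as.character(utils::packageVersion("brainctrl"))),
    summary = list(n_subjects = length(cohort),
                   n_regions = length(profiles$region_labels),
                   n_significant = nrow(sig),
                   n_significant_fdr = sum(comparison$p_fdr < config$alpha),
                   overall_accuracy = report_cv$overall_accuracy,
                   auc_mean = report_cv$auc_mean),
    comparison = comparison,
    cv = report_cv),
    class = "run_report")
  report
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Pipeline run: %d subjects x %d regions\n", s$n_subjects, s$n_regions))
  cat(sprintf("  significant regions (raw p < alpha): %d; FDR-surviving: %d\n",
              s$n_significant, s$n_significant_fdr))
  cat(sprintf("  CV pooled accuracy %.3f, mean AUC %.3f\n",
              s$overall_accuracy, s$auc_mean))
  cat(sprintf("  artifacts under %s\n", x$config$output_dir))
  invisible(x)
}
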