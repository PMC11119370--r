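## Synthetic two-group cohort generator.
##
## Emulates a resting-state fMRI case-control study at the ROI level:
## a modular ground-truth coupling network, a group-specific alteration
## localized to a set of effect regions, and per-subject BOLD-like time
## series drawn from a multivariate Gaussian with AR(1) temporal
## smoothing plus white measurement noise.

## Default indices of the eight altered regions: the AAL-90 parcels
## reported as group-discriminating in the emulated study design
## (mid-cingulate L, parahippocampal R, superior parietal L, paracentral
## lobule L/R, thalamus L/R, inferior temporal R).
DEFAULT_EFFECT_REGIONS <- c(33L, 40L, 59L, 69L, 70L, 77L, 78L, 90L)

#' Cohort-generation configuration
#'
#' Bundles and validates every knob of the synthetic cohort. Defaults
#' emulate the study design the package targets: 130 group-A (healthy
#' control-like) and 156 group-B (patient-like) subjects, 90 AAL regions,
#' 950 timepoints at TR = 0.5 s, and a connectivity alteration confined
#' to eight atlas regions.
#'
#' @param n_group_a,n_group_b subjects per group (labels 0 and 1).
#' @param n_regions number of ROIs.
#' @param n_timepoints timepoints per subject.
#' @param tr_seconds sampling interval in seconds.
#' @param effect_regions 1-based region indices carrying the group effect.
#' @param effect_multiplier factor applied in group B to every coupling
#'   incident to an effect region; 1 = no group difference.
#' @param subject_jitter_sd sd of the symmetric Gaussian jitter added to
#'   the group network per subject (between-subject variability).
#' @param noise_sd sd of additive white measurement noise.
#' @param ar1_coefficient AR(1) temporal smoothing coefficient in `[0, 1)`.
#' @param n_modules,within_weight,between_weight,weight_sd ground-truth
#'   network structure, see [build_group_network()].
#' @param seed master seed; all per-subject streams derive from it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_group_a = 130L, n_group_b = 156L,
                          n_regions = 90L, n_timepoints = 950L,
                          tr_seconds = 0.5,
                          effect_regions = DEFAULT_EFFECT_REGIONS,
                          effect_multiplier = 0.85,
                          subject_jitter_sd = 0.05, noise_sd = 0.2,
                          ar1_coefficient = 0.3,
                          n_modules = 6L, within_weight = 0.4,
                          between_weight = 0.1, weight_sd = 0.05,
                          seed = 1L) {
  cfg <- list(
    n_group_a = check_count(n_group_a, "n_group_a"),
    n_group_b = check_count(n_group_b, "n_group_b"),
    n_regions = check_count(n_regions, "n_regions"),
    n_timepoints = check_count(n_timepoints, "n_timepoints", min = 2),
    tr_seconds = tr_seconds,
    effect_regions = as.integer(effect_regions),
    effect_multiplier = effect_multiplier,
    subject_jitter_sd = subject_jitter_sd,
    noise_sd = noise_sd,
    ar1_coefficient = ar1_coefficient,
    n_modules = check_count(n_modules, "n_modules"),
    within_weight = within_weight,
    between_weight = between_weight,
    weight_sd = weight_sd,
    seed = check_count(seed, "seed", min = 0)
  )
  if (cfg$tr_seconds <= 0) stop_invalid("tr_seconds must be positive")
  if (length(cfg$effect_regions) &&
      (min(cfg$effect_regions) < 1 || max(cfg$effect_regions) > cfg$n_regions))
    stop_invalid("effect_regions must lie in [1, n_regions]")
  if (cfg$effect_multiplier <= 0) stop_invalid("effect_multiplier must be > 0")
  if (cfg$ar1_coefficient < 0 || cfg$ar1_coefficient >= 1)
    stop_invalid("ar1_coefficient must be in [0, 1)")
  if (cfg$subject_jitter_sd < 0 || cfg$noise_sd < 0 || cfg$weight_sd < 0)
    stop_invalid("standard deviations must be non-negative")
  class(cfg) <- "cohort_config"
  cfg
}

#' Build a modular ground-truth coupling network
#'
#' Regions are split into `n_modules` contiguous blocks; couplings within
#' a block are drawn around `within_weight` and couplings across blocks
#' around `between_weight`, each with Gaussian jitter of sd `weight_sd`.
#' The result is symmetric with a zero diagonal.
#'
#' @inheritParams cohort_config
#' @param group_tag label stored on the network (e.g. "A" or "B").
#' @return a `ground_truth_network`: list with `weights` (symmetric
#'   matrix), `region_labels` and `group_tag`.
#' @export
#' @examples
#' net <- build_group_network(10, n_modules = 2, seed = 1)
#' isSymmetric(net$weights)
build_group_network <- function(n_regions, n_modules = 1L,
                                within_weight = 0.4, between_weight = 0.1,
                                weight_sd = 0.05, seed = 1L,
                                group_tag = "A") {
  n_regions <- check_count(n_regions, "n_regions")
  n_modules <- check_count(n_modules, "n_modules")
  if (n_regions < n_modules)
    stop_invalid("n_regions (%d) must be >= n_modules (%d)", n_regions, n_modules)
  if (weight_sd < 0) stop_invalid("weight_sd must be >= 0")
  membership <- sort(rep_len(seq_len(n_modules), n_regions))
  base <- ifelse(outer(membership, membership, "=="), within_weight, between_weight)
  set.seed(mix_seed(seed, 101))
  jitter <- matrix(stats::rnorm(n_regions^2, sd = weight_sd), n_regions)
  jitter <- (jitter + t(jitter)) / 2
  w <- base + jitter
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  diag(w) <- 0
  structure(list(weights = w,
                 region_labels = default_region_labels(n_regions),
                 module_membership = membership,
                 group_tag = group_tag),
            class = "ground_truth_network")
}

#' Scale couplings incident to effect regions
#'
#' Returns a copy of the network in which every coupling touching an
#' effect region is multiplied by `effect_multiplier`; couplings between
#' two non-effect regions are untouched. Symmetry and the zero diagonal
#' are preserved (a coupling between two effect regions is scaled once).
#'
#' @param network a `ground_truth_network`.
#' @param effect_regions 1-based region indices.
#' @param effect_multiplier positive scale factor.
#' @export
inject_group_effect <- function(network, effect_regions, effect_multiplier) {
  stopifnot(inherits(network, "ground_truth_network"))
  n <- nrow(network$weights)
  effect_regions <- as.integer(effect_regions)
  if (length(effect_regions) &&
      (min(effect_regions) < 1 || max(effect_regions) > n))
    stop_invalid("effect_regions out of range [1, %d]", n)
  if (effect_multiplier <= 0) stop_invalid("effect_multiplier must be > 0")
  incident <- matrix(FALSE, n, n)
  incident[effect_regions, ] <- TRUE
  incident[, effect_regions] <- TRUE
  w <- network$weights
  w[incident] <- w[incident] * effect_multiplier
  diag(w) <- 0
  out <- network
  out$weights <- w
  out$group_tag <- "B"
  out
}

## Positive-definite lift of a coupling matrix: Sigma = K + lambda * I
## with lambda chosen so the smallest eigenvalue of Sigma is >= floor.
coupling_covariance <- function(weights, floor = 0.1) {
  ev_min <- min(eigen(weights, symmetric = TRUE, only.values = TRUE)$values)
  lambda <- max(0, floor - ev_min)
  sigma <- weights + diag(lambda, nrow(weights))
  list(sigma = sigma, lambda = lambda)
}

#' Sample one subject's ROI time series from a coupling network
#'
#' Builds a subject-specific coupling matrix (group network plus
#' symmetric Gaussian jitter), lifts it to a positive-definite covariance
#' `Sigma = coupling + lambda I` (smallest eigenvalue of Sigma >= 0.1),
#' draws rows from N(0, Sigma), applies recursive AR(1) smoothing
#' column-wise, and adds white noise.
#'
#' @param network a `ground_truth_network`.
#' @param n_timepoints rows of the output.
#' @param tr_seconds sampling interval (s).
#' @param subject_jitter_sd,noise_sd,ar1_coefficient see [cohort_config()].
#' @param seed integer seed; output is bit-identical for a fixed seed.
#' @param subject_id,group_label metadata stored on the result.
#' @return a `roi_timeseries`: list with `values` (timepoints x regions),
#'   `subject_id`, `group_label`, `tr_seconds`, `region_labels`.
#' @export
sample_subject_timeseries <- function(network, n_timepoints, tr_seconds = 0.5,
                                      subject_jitter_sd = 0, noise_sd = 0,
                                      ar1_coefficient = 0, seed = 1L,
                                      subject_id = "subj", group_label = 0L) {
  stopifnot(inherits(network, "ground_truth_network"))
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 2)
  if (ar1_coefficient < 0 || ar1_coefficient >= 1)
    stop_invalid("ar1_coefficient must be in [0, 1)")
  n <- nrow(network$weights)
  set.seed(seed)
  coupling <- network$weights
  if (subject_jitter_sd > 0) {
    j <- matrix(stats::rnorm(n^2, sd = subject_jitter_sd), n)
    j <- (j + t(j)) / 2
    diag(j) <- 0
    coupling <- coupling + j
  }
  sigma <- coupling_covariance(coupling)$sigma
  cf <- chol(sigma)
  x <- matrix(stats::rnorm(n_timepoints * n), n_timepoints, n) %*% cf
  if (ar1_coefficient > 0)
    x <- apply(x, 2, function(col)
      as.numeric(stats::filter(col, ar1_coefficient, method = "recursive")))
  if (noise_sd > 0)
    x <- x + matrix(stats::rnorm(n_timepoints * n, sd = noise_sd),
                    n_timepoints, n)
  colnames(x) <- network$region_labels
  structure(list(subject_id = subject_id,
                 group_label = as.integer(group_label),
                 values = x,
                 tr_seconds = tr_seconds,
                 region_labels = network$region_labels),
            class = "roi_timeseries")
}

#' Generate a full two-group cohort
#'
#' Group-A subjects (label 0) are drawn from the base network; group-B
#' subjects (label 1) from the effect-injected network. Each subject gets
#' an independent seed mixed from `config$seed`, the group and the
#' subject index, so the cohort is reproducible and order-independent.
#'
#' @param config a [cohort_config()].
#' @return a list of `roi_timeseries`, class `roi_cohort`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_group_a = 3, n_group_b = 4,
#'   n_regions = 10, n_timepoints = 50, n_modules = 2, seed = 7))
#' length(cohort)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  base <- build_group_network(config$n_regions, config$n_modules,
                              config$within_weight, config$between_weight,
                              config$weight_sd, seed = config$seed,
                              group_tag = "A")
  altered <- inject_group_effect(base, config$effect_regions,
                                 config$effect_multiplier)
  one_group <- function(net, n, label) {
    lapply(seq_len(n), function(i) {
      sample_subject_timeseries(
        net, config$n_timepoints, config$tr_seconds,
        config$subject_jitter_sd, config$noise_sd, config$ar1_coefficient,
        seed = mix_seed(config$seed, label, i),
        subject_id = sprintf("%s%03d", if (label == 0) "HC" else "PT", i),
        group_label = label)
    })
  }
  cohort <- c(one_group(base, config$n_group_a, 0L),
              one_group(altered, config$n_group_b, 1L))
  structure(cohort, class = "roi_cohort", config = config)
}

#' Write a cohort to disk as per-subject TSV files plus a manifest
#'
#' @param cohort an `roi_cohort` (or plain list of `roi_timeseries`).
#' @param dir output directory, created if missing.
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(ts) {
    f <- file.path(dir, paste0(ts$subject_id, ".tsv"))
    utils::write.table(ts$values, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    data.frame(subject_id = ts$subject_id, group_label = ts$group_label,
               path = f, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mpath)
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI time series: subject %s (group %d), %d timepoints x %d regions, TR %.3g s\n",
              x$subject_id, x$group_label, nrow(x$values), ncol(x$values),
              x$tr_seconds))
  invisible(x)
}

#' @export
print.roi_cohort <- function(x, ...) {
  labs <- vapply(x, `[[`, integer(1), "group_label")
  cat(sprintf("Synthetic cohort: %d subjects (%d group A, %d group B)\n",
              length(x), sum(labs == 0), sum(labs == 1)))
  invisible(x)
}
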