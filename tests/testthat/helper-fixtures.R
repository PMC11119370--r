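# Shared fixtures: everything is generated in code at test time.

# A small, fast cohort configuration used by most unit tests.
tiny_config <- function(n_group_a = 8, n_group_b = 10, seed = 11, ...) {
  cohort_config(n_group_a = n_group_a, n_group_b = n_group_b, n_regions = 12,
                n_timepoints = 80, effect_regions = c(2, 5, 9),
                effect_multiplier = 0.6, n_modules = 3, seed = seed, ...)
}

# Random Schur-stable symmetric system of size n.
random_stable_system <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, -1, 1), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  stabilize_adjacency(m)
}

# Independent AUC oracle: concordant-pair counting.
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Independent Mann-Whitney U oracle: exhaustive pair counting
# (number of x > y pairs, ties counted 1/2).
pair_count_u <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Memoized full-scale profile sets for the slow acceptance checks, so
# several criteria can share one generated cohort per (multiplier, seed).
.accept_cache <- new.env(parent = emptyenv())
full_scale_profiles <- function(effect_multiplier, seed) {
  key <- sprintf("m%s_s%d", format(effect_multiplier), seed)
  if (is.null(.accept_cache[[key]])) {
    cfg <- cohort_config(effect_multiplier = effect_multiplier, seed = seed)
    .accept_cache[[key]] <- profiles_for_cohort(fc_for_cohort(generate_cohort(cfg)))
  }
  .accept_cache[[key]]
}
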