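test_that("group networks have the stated block structure", {
  # zero-jitter, one module: every off-diagonal coupling is the within weight
  net <- build_group_network(4, n_modules = 1, within_weight = 0.5,
                             weight_sd = 0, seed = 1)
  expect_equal(diag(net$weights), rep(0, 4))
  off <- net$weights[upper.tri(net$weights)]
  expect_equal(off, rep(0.5, 6))

  # seed determinism at study scale
  a <- build_group_network(90, 6, 0.4, 0.1, 0.05, seed = 7)
  b <- build_group_network(90, 6, 0.4, 0.1, 0.05, seed = 7)
  expect_identical(a$weights, b$weights)

  # enumerate module membership: within-module couplings are larger on
  # average than between-module couplings when the weights say so
  net <- build_group_network(10, n_modules = 2, within_weight = 0.4,
                             between_weight = 0.1, weight_sd = 0.05, seed = 3)
  same <- outer(net$module_membership, net$module_membership, "==")
  diag(same) <- NA
  expect_gt(mean(net$weights[which(same)]),
            mean(net$weights[which(!same)]))

  expect_error(build_group_network(0, 1), "n_regions")
  expect_error(build_group_network(3, 5), "n_modules")
})

test_that("injected group effects scale exactly the incident couplings", {
  net <- build_group_network(4, 1, within_weight = 0.5, weight_sd = 0, seed = 1)

  # identity multiplier leaves the network untouched
  expect_equal(inject_group_effect(net, c(1, 3), 1)$weights, net$weights)

  # single effect region: its row/column scale, the rest stay put
  out <- inject_group_effect(net, 1, 0.6)$weights
  expect_equal(out[1, 2:4], rep(0.3, 3))
  expect_equal(out[2:4, 1], rep(0.3, 3))
  expect_equal(out[2:4, 2:4][upper.tri(matrix(0, 3, 3))], rep(0.5, 3))
  expect_true(isSymmetric(out))
  expect_equal(diag(out), rep(0, 4))

  # all regions: global scaling
  expect_equal(inject_group_effect(net, 1:4, 2)$weights, 2 * net$weights)

  expect_error(inject_group_effect(net, 5, 0.5), "out of range")
})

test_that("subject time series follow the constructed covariance", {
  # zero network: regions are independent, correlations vanish at large T
  znet <- build_group_network(3, 1, within_weight = 0, weight_sd = 0, seed = 1)
  ts <- sample_subject_timeseries(znet, 5000, noise_sd = 1, seed = 4)
  r <- cor(ts$values)
  expect_lt(max(abs(r[upper.tri(r)])), 0.1)

  # 2-region coupling 0.8: closed-form correlation from Sigma = K + lambda I
  # with lambda lifting the smallest eigenvalue (-0.8) to 0.1
  net2 <- build_group_network(2, 1, within_weight = 0.8, weight_sd = 0, seed = 1)
  sigma <- net2$weights + diag(0.9, 2)
  r_expected <- sigma[1, 2] / sqrt(sigma[1, 1] * sigma[2, 2])
  ts2 <- sample_subject_timeseries(net2, 5000, seed = 9)
  expect_lt(abs(cor(ts2$values)[1, 2] - r_expected), 0.05)

  # determinism
  t1 <- sample_subject_timeseries(net2, 100, subject_jitter_sd = 0.05,
                                  noise_sd = 0.2, ar1_coefficient = 0.3, seed = 12)
  t2 <- sample_subject_timeseries(net2, 100, subject_jitter_sd = 0.05,
                                  noise_sd = 0.2, ar1_coefficient = 0.3, seed = 12)
  expect_identical(t1$values, t2$values)

  expect_error(sample_subject_timeseries(net2, 1), "n_timepoints")
})

test_that("cohorts have exact group sizes and are seed-reproducible", {
  cfg <- tiny_config()
  cohort <- generate_cohort(cfg)
  labs <- vapply(cohort, `[[`, integer(1), "group_label")
  expect_length(cohort, 18)
  expect_equal(sum(labs == 0), 8)
  expect_equal(sum(labs == 1), 10)
  expect_false(anyDuplicated(vapply(cohort, `[[`, character(1), "subject_id")) > 0)

  cohort2 <- generate_cohort(tiny_config())
  expect_identical(lapply(cohort, `[[`, "values"),
                   lapply(cohort2, `[[`, "values"))

  # every subject matrix is finite and correctly shaped
  for (ts in cohort) {
    expect_equal(dim(ts$values), c(80L, 12L))
    expect_true(all(is.finite(ts$values)))
    expect_length(ts$region_labels, 12)
  }
})

test_that("cohort round-trips through the manifest on disk", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(tiny_config(seed = 21))
  manifest <- write_cohort(cohort, dir)
  back <- fc_for_cohort(manifest)
  direct <- fc_for_cohort(cohort)
  expect_length(back, length(direct))
  # TSV text round-trip preserves values to printed precision
  expect_equal(back[[3]]$values, direct[[3]]$values, tolerance = 1e-6)
  expect_identical(vapply(back, `[[`, integer(1), "group_label"),
                   vapply(direct, `[[`, integer(1), "group_label"))
})

test_that("effect direction is consistent across seeds", {
  # multiplier < 1 weakens couplings of effect regions in group B; the
  # group-mean average controllability in those regions must shift the
  # same way for every seed
  signs <- vapply(1:5, function(s) {
    cfg <- tiny_config(seed = 100 + s)
    prof <- profiles_for_cohort(fc_for_cohort(generate_cohort(cfg)))
    g <- prof$group_label
    d <- colMeans(prof$values[g == 0, cfg$effect_regions, drop = FALSE]) -
      colMeans(prof$values[g == 1, cfg$effect_regions, drop = FALSE])
    sign(mean(d))
  }, numeric(1))
  expect_true(all(signs == signs[1]))
})

test_that("seed mixing is deterministic, order-sensitive and in range", {
  expect_identical(mix_seed(42, 1, 17), mix_seed(42, 1, 17))
  expect_false(mix_seed(42, 1, 17) == mix_seed(42, 17, 1))
  s <- vapply(1:500, function(i) mix_seed(1, 0, i), integer(1))
  expect_false(anyDuplicated(s) > 0)
  expect_true(all(s >= 1 & s < 2^31 - 1))
})

test_that("configuration validation rejects bad parameters", {
  expect_error(cohort_config(n_group_a = 0), "n_group_a")
  expect_error(cohort_config(effect_regions = 91), "effect_regions")
  expect_error(cohort_config(effect_multiplier = 0), "effect_multiplier")
  expect_error(cohort_config(ar1_coefficient = 1), "ar1_coefficient")
  expect_error(cohort_config(noise_sd = -1), "non-negative")
})

test_that("the bundled AAL-90 fixture matches the atlas layout", {
  labels <- aal90_labels()
  expect_equal(nrow(labels), 90)
  expect_equal(labels$name[c(33, 40, 59, 69, 70, 77, 78, 90)],
               c("Cingulum_Mid_L", "ParaHippocampal_R", "Parietal_Sup_L",
                 "Paracentral_Lobule_L", "Paracentral_Lobule_R",
                 "Thalamus_L", "Thalamus_R", "Temporal_Inf_R"))
  # 90-region cohorts pick the atlas names up automatically
  net <- build_group_network(90, 6, seed = 1)
  expect_identical(net$region_labels, labels$name)
})
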