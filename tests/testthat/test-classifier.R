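toy_blobs <- function(n = 100, separation = 5, d = 2, seed = 91) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * d), n, d) + separation * y
  list(x = x, y = y)
}

toy_features <- function(n = 60, separation = 2, seed = 92) {
  b <- toy_blobs(n, separation, d = 3, seed = seed)
  structure(list(x = b$x, feature_names = paste0("f", 1:3),
                 region_ids = 1:3, y = b$y),
            class = "feature_matrix")
}

test_that("feature selection picks significant regions in atlas order", {
  prof <- profiles_for_cohort(fc_for_cohort(generate_cohort(tiny_config(seed = 81))))
  tab <- compare_groups(prof)

  # forced atlas list overrides the p-value filter and sorts by id
  fm <- select_features(prof, regions = c(9, 2, 5))
  expect_equal(fm$region_ids, c(2, 5, 9))
  expect_equal(fm$feature_names, prof$region_labels[c(2, 5, 9)])
  expect_equal(fm$x, prof$values[, c(2, 5, 9)], ignore_attr = TRUE)
  expect_identical(fm$y, prof$group_label)

  # alpha = 1 keeps every region
  expect_equal(ncol(select_features(prof, tab, alpha = 1)$x), 12)

  # the default filter is the raw t-test p at alpha
  fm2 <- select_features(prof, tab, alpha = 0.05)
  expect_equal(fm2$region_ids, sort(tab$region_id[tab$p_t < 0.05]))

  expect_error(select_features(prof, tab, alpha = 1e-12), "no region")
  expect_error(select_features(prof, regions = 99), "out of range")
})

test_that("stratified folds balance classes and partition the cohort", {
  labels <- rep(c(0L, 1L), c(130, 156))
  fold <- stratified_folds(labels, k = 10, seed = 7)
  expect_length(fold, 286)
  expect_setequal(unique(fold), 1:10)
  sizes <- table(fold)
  expect_true(all(sizes %in% c(28, 29)))
  per_fold_class0 <- table(fold[labels == 0])
  expect_true(all(abs(per_fold_class0 - 13) <= 1))

  # leave-one-out degenerate: singleton folds per class-balanced case
  lab2 <- rep(c(0L, 1L), 3)
  expect_setequal(stratified_folds(lab2, k = 3, seed = 1), 1:3)

  expect_identical(stratified_folds(labels, 10, seed = 5),
                   stratified_folds(labels, 10, seed = 5))
  expect_error(stratified_folds(rep(c(0, 1), c(4, 50)), k = 10), "at least k")
})

test_that("the MLP trains deterministically and separates easy data", {
  b <- toy_blobs()
  arch <- mlp_architecture(epochs = 60)
  model <- train_mlp(b$x, b$y, arch, seed = 3)
  p <- predict(model, b$x)
  expect_true(all(p > 0 & p < 1))
  expect_gte(mean((p >= 0.5) == b$y), 0.95)

  model2 <- train_mlp(b$x, b$y, arch, seed = 3)
  expect_identical(predict(model2, b$x), p)

  expect_error(train_mlp(b$x, rep(1, nrow(b$x)), arch), "each class")
})

test_that("ROC/AUC matches the pair-counting oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)

  set.seed(95)
  for (i in 1:15) {
    n <- sample(5:60, 1)
    scores <- round(runif(n), 2)  # force ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, pair_count_auc(scores, labels), tolerance = 1e-10)
    expect_equal(r$roc_points[1, ], data.frame(fpr = 0, tpr = 0),
                 ignore_attr = TRUE)
    expect_equal(unlist(r$roc_points[nrow(r$roc_points), ]),
                 c(fpr = 1, tpr = 1))
    expect_true(all(diff(r$roc_points$fpr) >= 0))
    expect_true(all(diff(r$roc_points$tpr) >= 0))
    # invariance under strictly increasing transforms
    expect_equal(roc_auc(exp(2 * scores), labels)$auc, r$auc)
  }

  # chance level for independent scores
  set.seed(96)
  expect_lt(abs(roc_auc(runif(2000), rbinom(2000, 1, 0.5))$auc - 0.5), 0.05)

  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("trapezoidal AUC agrees with pROC on random inputs", {
  skip_if_not_installed("pROC")
  set.seed(97)
  scores <- runif(80)
  labels <- rbinom(80, 1, 0.5)
  ours <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("cross-validation partitions subjects and aggregates folds", {
  fm <- toy_features(n = 80, separation = 2.5)
  arch <- mlp_architecture(epochs = 30)
  cv <- cross_validate(fm, arch, k = 5, seed = 13)

  expect_length(cv$fold_results, 5)
  expect_equal(sum(cv$pooled_confusion), 80)
  # pooled matrix equals the sum of fold counts
  counts <- colSums(do.call(rbind, lapply(cv$fold_results, function(fr)
    c(fr$tn, fr$fp, fr$fn, fr$tp))))
  expect_equal(as.numeric(t(cv$pooled_confusion)), unname(counts))
  for (fr in cv$fold_results) {
    expect_equal(fr$tp + fr$tn + fr$fp + fr$fn,
                 sum(cv$fold_assignment == fr$fold_index))
    if (fr$tp + fr$fn > 0) expect_equal(fr$tpr, fr$tp / (fr$tp + fr$fn))
    if (fr$fp + fr$tn > 0) expect_equal(fr$fpr, fr$fp / (fr$fp + fr$tn))
  }
  # separable data: clearly above chance
  expect_gt(cv$auc_mean, 0.9)

  # determinism of the whole report
  cv2 <- cross_validate(fm, arch, k = 5, seed = 13)
  expect_identical(cv2$pooled_confusion, cv$pooled_confusion)
  expect_identical(cv2$auc_mean, cv$auc_mean)
})

test_that("label-shuffled features score at chance", {
  fm <- toy_features(n = 80, separation = 2.5)
  set.seed(14)
  fm$y <- sample(fm$y)
  cv <- cross_validate(fm, mlp_architecture(epochs = 30), k = 5, seed = 14)
  expect_gt(cv$overall_accuracy, 0.3)
  expect_lt(cv$overall_accuracy, 0.7)
  expect_gt(cv$auc_mean, 0.3)
  expect_lt(cv$auc_mean, 0.7)
})

test_that("CV reports serialize to JSON with the pooled matrix", {
  fm <- toy_features(n = 40, separation = 3)
  cv <- cross_validate(fm, mlp_architecture(epochs = 10), k = 4, seed = 15)
  path <- withr::local_tempfile(fileext = ".json")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_cv_report(cv, path, confusion_tsv = tsv)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$overall_accuracy, cv$overall_accuracy)
  expect_equal(length(back$folds$auc), 4)
  expect_equal(sum(back$pooled_confusion), 40)
  expect_true(file.exists(tsv))
})
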