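test_that("confusion metrics reproduce the reported detection arithmetic", {
  # bronchoscopy: 40 of 78 cancers detected -> 51% (95% CI, 40-62%)
  ci <- wilson_ci(40, 78)
  truth <- rep(1, 78); calls <- rep(c(1, 0), c(40, 38))
  cm <- confusion_metrics(truth, calls)
  expect_identical(unname(cm$display["sensitivity"]), 51)
  expect_equal(unname(cm$sensitivity), unname(ci), tolerance = 1e-12)
  expect_identical(round(100 * unname(cm$sensitivity[c("lower", "upper")])),
                   c(40, 62))
  # classifier among non-diagnostic cancers: 34 of 38 -> 89%
  cm2 <- confusion_metrics(rep(1, 38), rep(c(1, 0), c(34, 4)))
  expect_identical(unname(cm2$display["sensitivity"]), 89)
  # combined: 74 of 78 -> 95%
  cm3 <- confusion_metrics(rep(1, 78), rep(c(1, 0), c(74, 4)))
  expect_identical(unname(cm3$display["sensitivity"]), 95)
})

test_that("confusion metrics: counts are consistent and zero denominators are NA", {
  set.seed(7)
  truth <- rbinom(100, 1, 0.4); calls <- rbinom(100, 1, 0.5)
  cm <- confusion_metrics(truth, calls)
  expect_identical(cm$tp + cm$fp + cm$tn + cm$fn, 100L)
  expect_identical(cm$tp + cm$fn, sum(truth))
  expect_equal(cm$sensitivity[["estimate"]] * (cm$tp + cm$fn), cm$tp,
               tolerance = 1e-12)
  # no positive calls -> PPV undefined, not zero
  cm2 <- confusion_metrics(truth, rep(0L, 100))
  expect_true(is.na(cm2$ppv[["estimate"]]))
  expect_error(confusion_metrics(truth, calls, subgroup = rep(FALSE, 100)),
               "empty subgroup")
})

test_that("bronchoscopy combination is the OR rule", {
  expect_identical(combine_with_bronchoscopy(1L, 0L), 1L)
  expect_identical(combine_with_bronchoscopy(0L, 0L), 0L)
  expect_identical(combine_with_bronchoscopy(0L, 1L), 1L)
  b <- c(1, 1, 0, 0); cl <- c(0, 1, 0, 1)
  expect_identical(combine_with_bronchoscopy(b, cl), c(1L, 1L, 0L, 1L))
})

test_that("AUC equals brute-force concordant-pair counting", {
  set.seed(11)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    truth <- rbinom(n, 1, 0.4)
    if (length(unique(truth)) < 2) next
    scores <- round(rnorm(n, truth), 1)  # rounding creates ties
    expect_equal(roc_auc(scores, truth)$auc, auc_pairs_oracle(scores, truth),
                 tolerance = 1e-12)
  }
  expect_identical(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC is invariant under monotone transforms and null-calibrated", {
  set.seed(13)
  truth <- rbinom(300, 1, 0.5)
  scores <- rnorm(300, truth)
  a1 <- roc_auc(scores, truth)$auc
  expect_equal(roc_auc(plogis(3 * scores - 1), truth)$auc, a1, tolerance = 1e-12)
  null_scores <- rnorm(1000)
  null_truth <- rbinom(1000, 1, 0.5)
  expect_true(abs(roc_auc(null_scores, null_truth)$auc - 0.5) < 0.05)
  ci <- roc_auc(scores, truth, ci = TRUE)$ci
  expect_true(ci["lower"] < a1 && a1 < ci["upper"])
})

test_that("model comparison: identity, symmetry, and planted difference", {
  set.seed(17)
  truth <- rbinom(400, 1, 0.5)
  s <- plogis(rnorm(400, 1.5 * truth))
  cmp_same <- compare_models(s, s, truth)
  expect_identical(cmp_same$p, 1)
  expect_identical(cmp_same$delta, 0)
  # anti-correlated duplicate: AUCs sum to 1
  a <- roc_auc(s, truth)$auc; b <- roc_auc(1 - s, truth)$auc
  expect_equal(a + b, 1, tolerance = 1e-12)
  # stronger model beats a noised-down version
  weak <- plogis(rnorm(400, 0.3 * truth))
  cmp <- compare_models(s, weak, truth)
  expect_gt(cmp$delta, 0)
  expect_lt(cmp$p, 0.05)
  expect_error(compare_models(s, weak[-1], truth), "same samples")
})

test_that("the clinical-factors model predicts cancer from reported covariates", {
  sim <- simulate_cohort(cohort_config(n_genes = 400, n_clusters = 2,
                                       genes_per_cluster = 5, n_sex_genes = 2,
                                       n_smoking_genes = 2, n_py_genes = 2,
                                       cluster_effects = c(1, -1)), seed = 19)
  s <- clinical_model_scores(sim$dataset)
  # age and pack-years differ by class in the default cohort -> AUC > 0.5
  expect_gt(roc_auc(s, sim$dataset$phenotypes$cancer_status)$auc, 0.6)
})

test_that("cv harness never leaks holdout samples and tracks planted signal", {
  sim <- simulate_cohort(cohort_config(), seed = 127)
  cfg <- derive_config(cv_reps = 15)
  cv <- suppressWarnings(cv_harness(sim$dataset, cfg, reps = 3, seed = 3))
  # structural leakage check: train and holdout ids disjoint in every rep
  for (i in seq_along(cv$folds)) {
    expect_length(intersect(cv$train_ids[[i]], cv$folds[[i]]), 0)
    expect_setequal(c(cv$train_ids[[i]], cv$folds[[i]]),
                    sim$dataset$phenotypes$sample_id)
  }
  expect_gte(cv$pooled_auc, 0.85)
  # reproducible fold assignment
  cv2 <- suppressWarnings(cv_harness(sim$dataset, cfg, reps = 3, seed = 3))
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$pooled_auc, cv2$pooled_auc)
})

test_that("packaged cohort tables reproduce the reported exact tests", {
  stats <- reproduce_cohort_stats()
  expect_identical(round(unname(stats$fisher_p["sex"]), 3), 0.178)
  expect_identical(round(unname(stats$fisher_p["smoking_status"]), 3), 0.107)
  expect_identical(round(unname(stats$fisher_p["mass_location"]), 3), 0.018)
  expect_identical(round(100 * stats$sensitivity$bronchoscopy[["estimate"]]), 51)
  expect_identical(round(100 * stats$sensitivity$classifier_nondiagnostic[["estimate"]]), 89)
  expect_identical(round(100 * stats$sensitivity$combined[["estimate"]]), 95)
})
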