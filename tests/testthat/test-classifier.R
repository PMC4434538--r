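test_that("cluster means are arithmetic means, invariant to member order", {
  x <- matrix(c(4, 6, 8, 10), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cm <- cluster_means(x, list(CA1 = c("g1", "g2")))
  expect_equal(unname(cm[, "CA1"]), c(5, 9))
  cm2 <- cluster_means(x, list(CA1 = c("g2", "g1")))
  expect_identical(cm, cm2)
  # constant cluster -> constant mean
  cmc <- cluster_means(matrix(7, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2"))),
                       list(CA1 = c("a", "b")))
  expect_true(all(cmc == 7))
  expect_error(cluster_means(x, list(CA1 = c("g1", "nope"))), "nope")
})

test_that("locked scorer matches independent Table 2 arithmetic", {
  m <- locked_classifier()
  # frozen: all features zero leaves only the intercept
  zero <- as.data.frame(as.list(setNames(rep(0, 10), names(m$coefficients))))
  expect_equal(classifier_score(m, zero), plogis(3.3173), tolerance = 1e-15)
  expect_identical(round(classifier_score(m, zero), 5), 0.96502)

  fv <- random_feature_table(200, seed = 71)
  expect_equal(classifier_score(m, fv),
               with(fv, locked_score_oracle(age, GG, GS, GPY, CA1, CA2, CA4,
                                            CA7, CA9, CA10)),
               tolerance = 1e-12)

  # regression fixture: one vector evaluated by hand arithmetic
  hand <- data.frame(age = 65, GG = 1, GS = 0.9, GPY = 0.8, CA1 = 6, CA2 = 7,
                     CA4 = 8, CA7 = 6.5, CA9 = 5, CA10 = 6)
  expect_equal(classifier_score(m, hand),
               locked_score_oracle(65, 1, 0.9, 0.8, 6, 7, 8, 6.5, 5, 6),
               tolerance = 1e-12)

  expect_error(classifier_score(m, fv[, -3]), "GS")
})

test_that("score respects the Table 2 coefficient signs (monotonicity)", {
  m <- locked_classifier()
  fv <- random_feature_table(50, seed = 73)
  s0 <- classifier_score(m, fv)
  for (feat in names(m$coefficients)) {
    fv2 <- fv; fv2[[feat]] <- fv2[[feat]] + 0.5
    s1 <- classifier_score(m, fv2)
    if (m$coefficients[[feat]] > 0) expect_true(all(s1 > s0), label = feat)
    else expect_true(all(s1 < s0), label = feat)
  }
  expect_true(all(s0 > 0 & s0 < 1))
})

test_that("classification is boundary-inclusive at the 0.65 threshold", {
  expect_identical(classify(0.65), 1L)
  expect_identical(classify(0.649999), 0L)
  expect_identical(classify(1.0), 1L)
  expect_identical(classify(0), 0L)
  expect_error(classify(1.2), "0,1")
})

test_that("the locked scorer is pure: identical input, identical output", {
  m <- locked_classifier()
  fv <- random_feature_table(20, seed = 79)
  expect_identical(classifier_score(m, fv), classifier_score(m, fv))
})

test_that("zero-penalty fit equals the unpenalized MLE", {
  sim <- simulate_classifier_features(locked_classifier(), n = 400, seed = 83)
  fit <- fit_penalized_logistic(as.matrix(sim$features), sim$status, penalty = 0)
  g <- glm(y ~ ., binomial, data = data.frame(y = sim$status, sim$features))
  expect_equal(c(fit$intercept, fit$coefficients), unname(coef(g)),
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("an infinite cluster penalty collapses the model onto the covariates", {
  sim <- simulate_classifier_features(locked_classifier(), n = 400, seed = 89)
  fit <- fit_final(sim$features, sim$status, penalty_clusters = 1e12)
  ca <- grep("^CA", names(fit$coefficients))
  expect_true(all(abs(fit$coefficients[ca]) < 1e-6))
  cov_only <- glm(y ~ age + GG + GS + GPY, binomial,
                  data = data.frame(y = sim$status, sim$features))
  expect_equal(fit$coefficients[c("age", "GG", "GS", "GPY")],
               coef(cov_only)[c("age", "GG", "GS", "GPY")],
               tolerance = 1e-4)
})

test_that("differential penalties shrink cluster features, not covariates", {
  sim <- simulate_classifier_features(locked_classifier(), n = 1000, seed = 97)
  f0 <- fit_final(sim$features, sim$status, penalty_clusters = 0)
  f10 <- fit_final(sim$features, sim$status, penalty_clusters = 10)
  ca <- grep("^CA", names(f0$coefficients))
  # ridge shrinks the cluster block as a whole
  expect_lt(sum(f10$coefficients[ca]^2), sum(f0$coefficients[ca]^2))
  expect_error(fit_penalized_logistic(as.matrix(sim$features), sim$status,
                                      penalty = -1), "non-negative")
  expect_error(fit_final(sim$features, rep(1, 1000)), "both classes")
})

test_that("threshold selection hits the target subgroup sensitivity", {
  set.seed(101)
  status <- rbinom(400, 1, 0.5)
  scores <- plogis(rnorm(400, 2 * status))
  th <- choose_threshold(scores, status, target_sensitivity = 0.9)
  expect_gte(mean(scores[status == 1] >= th), 0.9)
  # the next-larger candidate threshold must miss the target
  above <- sort(unique(scores))[sort(unique(scores)) > th]
  if (length(above))
    expect_lt(mean(scores[status == 1] >= above[1]), 0.9)

  # perfect separation: returns a threshold with sensitivity 1
  th2 <- choose_threshold(c(0.9, 0.95, 0.1, 0.2), c(1, 1, 0, 0),
                          target_sensitivity = 1)
  expect_identical(th2, 0.9)
  # unattainable target -> minimum score with warning
  expect_warning(th3 <- choose_threshold(c(0.5, 0.6, 0.4), c(1, 0, 1),
                                         target_sensitivity = 2),
                 "unattainable")
  expect_identical(th3, 0.4)
  expect_error(choose_threshold(c(0.5, 0.6), c(1, 1), 0.9), "both classes")
})

test_that("derivation on a planted cohort returns a working classifier", {
  sim <- simulate_cohort(cohort_config(classifier_genes = TRUE), seed = 103)
  model <- derive_classifier(sim$dataset, derive_config(cv_reps = 20))
  expect_s3_class(model, "airway_classifier")
  expect_true(all(grepl("^CA", names(model$clusters))))
  s <- predict(model, sim$dataset)
  expect_gt(roc_auc(s, sim$dataset$phenotypes$cancer_status)$auc, 0.9)
  # the recorded CV AUC beats the covariate-only baseline
  expect_gt(model$details$cv_auc, model$details$baseline_cv_auc)
  # threshold respects the ~90% sensitivity target in the intended subgroup
  nondx <- sim$dataset$phenotypes$bronchoscopy_diagnostic == 0
  calls <- classify(s, model$threshold)
  cm <- confusion_metrics(sim$dataset$phenotypes$cancer_status, calls,
                          subgroup = nondx)
  expect_gte(cm$sensitivity[["estimate"]], 0.85)
  # round-trips through JSON with identical scores
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  expect_identical(unname(predict(load_model(path), sim$dataset)), unname(s))
})
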