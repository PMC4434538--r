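test_that("locked CFGC formulas evaluate exactly as printed", {
  # genomic gender: strict '<' at the 7.5 cutpoint
  expect_identical(genomic_gender(7.4), 1L)
  expect_identical(genomic_gender(7.5), 0L)
  expect_identical(genomic_gender(12.0), 0L)

  # genomic smoking: independent direct evaluation of the printed form
  expect_equal(genomic_smoking(8, 9, 10), gs_oracle(8, 9, 10), tolerance = 1e-12)
  expect_identical(round(genomic_smoking(8, 9, 10), 5), 0.46608)
  # x = 0 -> 0.5: solve the linear form for TKT
  tkt0 <- (40.8579 - 0.4462 * 8 - 2.1298 * 9) / 1.8256
  expect_equal(genomic_smoking(8, 9, tkt0), 0.5, tolerance = 1e-12)
  # strictly decreasing in each input
  base <- genomic_smoking(8, 9, 10)
  expect_lt(genomic_smoking(8.5, 9, 10), base)
  expect_lt(genomic_smoking(8, 9.5, 10), base)
  expect_lt(genomic_smoking(8, 9, 10.5), base)

  # genomic pack-years
  expect_equal(genomic_pack_years(4, 3), gpy_oracle(4, 3), tolerance = 1e-12)
  expect_identical(round(genomic_pack_years(4, 3), 5), 0.68172)
  runx0 <- (5.1429 + 0.9506 * 3) / 2.1891
  expect_equal(genomic_pack_years(runx0, 3), 0.5, tolerance = 1e-12)
  expect_gt(genomic_pack_years(4.5, 3), genomic_pack_years(4, 3))

  expect_error(genomic_gender(NA_real_), "finite")
})

test_that("locked formulas are invariant to gene order and extra genes", {
  m <- locked_classifier()
  sim <- simulate_cohort(small_config(15, 10, classifier_genes = TRUE),
                         seed = 31)
  x <- sim$dataset$expression
  s1 <- predict(m, list(expression = x, age = sim$dataset$phenotypes$age))
  set.seed(1)
  x2 <- x[sample(nrow(x)), ]
  s2 <- predict(m, list(expression = x2, age = sim$dataset$phenotypes$age))
  expect_identical(s1, s2)
})

test_that("covariate gene selection recovers planted genes and respects p_cut", {
  cfg <- cohort_config(n_smoking_genes = 50, smoking_effect = 2, n_genes = 2000)
  sim <- simulate_cohort(cfg, seed = 37)
  sel <- select_covariate_genes(sim$dataset, "smoking_status")
  planted <- sim$truth$smoking_genes
  expect_true(all(planted %in% sel$gene))
  expect_gte(mean(sel$gene[1:50] %in% planted), 0.95)
  expect_true(!is.unsorted(sel$p))

  ph <- sim$dataset$phenotypes
  ph$smoking_status <- "current"
  d2 <- structure(list(expression = sim$dataset$expression, phenotypes = ph),
                  class = "airway_dataset")
  expect_error(select_covariate_genes(d2, "smoking_status"), "constant")
})

test_that("null cohorts select about the nominal false-positive count", {
  cfg <- cohort_config(n_genes = 10000, n_clusters = 1, genes_per_cluster = 2,
                       cluster_effects = 0, n_sex_genes = 1, sex_effect = 0,
                       n_smoking_genes = 1, smoking_effect = 0,
                       n_py_genes = 1, py_effect = 0)
  sim <- simulate_cohort(cfg, seed = 41)
  sel <- select_covariate_genes(sim$dataset, "smoking_status", p_cut = 0.001)
  expect_lt(nrow(sel), 30)  # expectation is 10, binomial sd ~3
})

test_that("a perfectly separating gene yields a threshold rule with AUC 1", {
  sim <- simulate_cohort(small_config(40, 20, classifier_genes = TRUE),
                         seed = 43)
  sel <- select_covariate_genes(sim$dataset, "sex")
  fit <- fit_cfgc(sim$dataset, "sex", sel$gene, n_genes = 1)
  expect_identical(fit$type, "threshold")
  expect_identical(fit$gene, "RPS4Y1")
  expect_identical(fit$auc, 1)
  gg <- apply_cfgc(fit, sim$dataset$expression)
  expect_identical(gg, as.numeric(sim$dataset$phenotypes$sex == "female"))
})

test_that("logistic CFGC fits select planted genes and discriminate", {
  sim <- simulate_cohort(cohort_config(classifier_genes = TRUE), seed = 47)
  sel <- select_covariate_genes(sim$dataset, "smoking_status")
  fit <- fit_cfgc(sim$dataset, "smoking_status", sel$gene, n_genes = 3, seed = 2)
  expect_identical(fit$type, "logistic")
  expect_lte(length(fit$genes), 3)
  expect_true(all(fit$genes %in% sel$gene))
  expect_gt(fit$auc, 0.9)
  gs <- apply_cfgc(fit, sim$dataset$expression)
  expect_true(all(gs > 0 & gs < 1))
  expect_error(fit_cfgc(sim$dataset, "smoking_status", character(0)), "empty")
})

test_that("derived CFGC coefficients are recoverable from locked-formula cohorts", {
  # simulate smoking status directly from the locked GS formula, refit, and
  # compare coefficients: parameter recovery at n = 2000, 15% relative
  # tolerance on the median estimate over 5 cohorts (the median keeps the
  # Monte-Carlo error well inside the tolerance)
  truth <- c(SLC7A11 = -0.4462, CLDN10 = -2.1298, TKT = -1.8256)
  one_fit <- function(seed) {
    set.seed(seed)
    n <- 2000
    x <- rbind(SLC7A11 = rnorm(n, 8, 1.5), CLDN10 = rnorm(n, 10.5, 1),
               TKT = rnorm(n, 10.6, 1),
               matrix(rnorm(20 * n, 7, 1), nrow = 20,
                      dimnames = list(sprintf("N%02d", 1:20), NULL)))
    colnames(x) <- sprintf("S%04d", 1:n)
    gs <- genomic_smoking(x["SLC7A11", ], x["CLDN10", ], x["TKT", ])
    ph <- data.frame(sample_id = colnames(x), cancer_status = rep_len(0:1, n),
                     sex = "female",
                     smoking_status = ifelse(runif(n) < gs, "current", "former"),
                     pack_years = 20, age = 60, stringsAsFactors = FALSE)
    d <- align_dataset(x, ph)
    fit <- fit_cfgc(d, "smoking_status", c("SLC7A11", "CLDN10", "TKT"),
                    n_genes = 3, seed = seed)
    fit$coefficients[names(truth)]
  }
  est <- apply(vapply(53:57, one_fit, numeric(3)), 1, median)
  expect_true(all(abs((est - truth) / truth) < 0.15))
})
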