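# airwayclassifier

Lung cancer leaves a detectable gene-expression signature in cytologically
normal epithelial cells of the proximal airway of current and former smokers
— the smoking "field of injury". This package implements a bronchial-airway
gene-expression classifier built on that signal for patients undergoing
diagnostic bronchoscopy, where it matters most when the bronchoscopy itself
is non-diagnostic: a sensitive, high-NPV genomic test can identify patients
unlikely to have cancer and spare them further invasive procedures. It is
aimed at computational biologists who want to apply the locked published
model, re-derive classifiers of the same family on their own cohorts, or
study the behaviour of the derivation procedure on simulated data.

## The model

A patient's score is a logistic regression

    score = exp(y) / (1 + exp(y)),   y = b0 + Σ b_i · x_i

over ten features:

| feature | meaning | genes |
|---|---|---|
| age | years, as reported | — |
| GG | genomic gender (1 = female), threshold rule | RPS4Y1 < 7.5 |
| GS | genomic smoking status, logistic form | SLC7A11, CLDN10, TKT |
| GPY | genomic pack-years, logistic form | RUNX1T1, AKR1C2 |
| CA1, CA2, CA4, CA7, CA9, CA10 | cancer cluster means (arithmetic mean of member-gene log2 expression) | 17 gene measurements in six clusters |

Calls are cancer-positive when score ≥ 0.65. The locked parameterization
(intercept 3.3173; coefficients for all ten features; the CFGC formulas; the
cluster memberships) ships as a package resource: `locked_classifier()`.

The package also implements the full derivation pipeline
(`derive_classifier()`): empirical-Bayes moderated-t gene selection for the
clinical-factor correlates and, against baseline-model residuals, for cancer
genes (|T| > 2.7); average-linkage correlation clustering with parsimonious
2–4-gene cluster representatives; cross-validated cluster subset selection;
and the final differentially penalized logistic fit (penalty 0 on
covariates, 10 on cluster means). Cross-platform validation support
(`mean_shift_adjust()`, `impute_missing_genes()`), diagnostic evaluation
(`confusion_metrics()`, `roc_auc()` with DeLong inference, `cv_harness()`)
and a synthetic-cohort generator with planted ground truth
(`simulate_cohort()`) round out the toolkit. See the methods vignette
(`vignettes/classifier-methods.Rmd`) for every modelling choice.

## Worked example

Score a simulated cohort that embeds the classifier's genes with planted
effects, then evaluate in the intended-use subgroup:

```r
library(airwayclassifier)

sim <- simulate_cohort(cohort_config(classifier_genes = TRUE), seed = 1)
m <- locked_classifier()
m
#> Bronchial airway gene-expression lung-cancer classifier
#>   10 features, 23 genes, decision threshold 0.65
#>   score = plogis(3.3173 + sum(b_i * x_i))

scores <- predict(m, sim$dataset)          # one score in (0,1) per sample
calls  <- classify(scores, m$threshold)    # 1 = cancer-positive
roc_auc(scores, sim$dataset$phenotypes$cancer_status)$auc
#> [1] 0.9224806

confusion_metrics(sim$dataset$phenotypes$cancer_status, calls,
                  subgroup = sim$dataset$phenotypes$bronchoscopy_diagnostic == 0,
                  label = "non-diagnostic bronchoscopy")
#> confusion summary [non-diagnostic bronchoscopy]: n=135 (TP 59, FP 68, TN 8, FN 0)
#>   sensitivity 100% (95% CI, 94-100%)
#>   specificity  11% (95% CI, 5-19%)
#>   npv         100% (95% CI, 68-100%)
#>   ppv          46% (95% CI, 38-55%)
```

The locked model discriminates well on this cohort (AUC 0.92) and misses no
cancer in the non-diagnostic subgroup, but its 0.65 threshold was calibrated
on the original training cohort, not on synthetic data — hence the low
specificity here. `derive_classifier(sim$dataset)` re-derives a classifier
(and a threshold targeting ~90% subgroup sensitivity) for the cohort at hand.

The published cohort statistics are reproducible from the packaged count
tables:

```r
reproduce_cohort_stats()$fisher_p
#>            sex smoking_status  mass_location
#>          0.178          0.107          0.018
```

A thin command-line wrapper with `simulate`, `score` and `adjust`
subcommands is installed at `inst/cli/airway-classifier.R`.

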