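#' @title Diagnostic performance evaluation
#' @description Confusion metrics with Wilson intervals, combination of the
#'   classifier with bronchoscopy (a positive bronchoscopy is definitive, so
#'   the combined call is the OR of the two), ROC/AUC with DeLong inference,
#'   paired model comparison, and a leakage-free cross-validation harness that
#'   reruns the entire derivation inside every fold.
#' @name evaluation
NULL

round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Confusion-matrix summary with Wilson intervals
#'
#' @param truth 0/1 cancer status.
#' @param calls 0/1 predicted status.
#' @param subgroup optional logical mask; metrics are computed within it.
#' @param label subgroup label carried in the output.
#' @return list of class `confusion_summary` with counts (`tp`, `fp`, `tn`,
#'   `fn`, `n`), `prevalence`, and `sensitivity`, `specificity`, `npv`, `ppv`
#'   each as `c(estimate, lower, upper)` (`NA` when the denominator is zero),
#'   plus display percentages rounded half-up.
#' @export
confusion_metrics <- function(truth, calls, subgroup = NULL, label = "all") {
  stopifnot(length(truth) == length(calls))
  if (!is.null(subgroup)) { truth <- truth[subgroup]; calls <- calls[subgroup] }
  if (!length(truth)) stop("empty subgroup")
  stopifnot(all(truth %in% 0:1), all(calls %in% 0:1))
  tp <- sum(truth == 1 & calls == 1); fn <- sum(truth == 1 & calls == 0)
  tn <- sum(truth == 0 & calls == 0); fp <- sum(truth == 0 & calls == 1)
  met <- function(x, n) if (n == 0) c(estimate = NA_real_, lower = NA_real_,
                                      upper = NA_real_) else wilson_ci(x, n)
  out <- list(label = label, tp = tp, fp = fp, tn = tn, fn = fn,
              n = tp + fp + tn + fn,
              prevalence = (tp + fn) / (tp + fp + tn + fn),
              sensitivity = met(tp, tp + fn),
              specificity = met(tn, tn + fp),
              npv = met(tn, tn + fn),
              ppv = met(tp, tp + fp))
  out$display <- vapply(out[c("sensitivity", "specificity", "npv", "ppv")],
                        function(ci) round_half_up(100 * ci[["estimate"]]),
                        numeric(1))
  class(out) <- "confusion_summary"
  out
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("confusion summary [%s]: n=%d (TP %d, FP %d, TN %d, FN %d)\n",
              x$label, x$n, x$tp, x$fp, x$tn, x$fn))
  for (m in c("sensitivity", "specificity", "npv", "ppv")) {
    ci <- x[[m]]
    if (is.na(ci[["estimate"]])) cat(sprintf("  %-11s undefined\n", m))
    else cat(sprintf("  %-11s %3.0f%% (95%% CI, %.0f-%.0f%%)\n", m,
                     round_half_up(100 * ci[["estimate"]]),
                     round_half_up(100 * ci[["lower"]]),
                     round_half_up(100 * ci[["upper"]])))
  }
  invisible(x)
}

#' Combine classifier calls with bronchoscopy
#'
#' A diagnostic bronchoscopy is definitive evidence of cancer, so the combined
#' procedure is positive iff bronchoscopy was diagnostic OR the classifier
#' called positive.
#'
#' @param bronch_diagnostic 0/1 bronchoscopy-diagnostic flag.
#' @param classifier_call 0/1 classifier call.
#' @return 0/1 combined call.
#' @export
combine_with_bronchoscopy <- function(bronch_diagnostic, classifier_call) {
  stopifnot(length(bronch_diagnostic) == length(classifier_call))
  as.integer(bronch_diagnostic == 1L | classifier_call == 1L)
}

#' ROC curve and AUC with DeLong inference
#'
#' AUC via the rank (Mann-Whitney) formulation with midrank tie handling;
#' the 95% CI uses DeLong's method.
#'
#' @param scores numeric scores (higher = more cancer-like).
#' @param truth 0/1 cancer status (both classes present).
#' @param ci compute the DeLong CI (needs >= 2 per class).
#' @return list with `auc`, `ci` (lower/upper or NULL), `curve`
#'   (data.frame of FPR/TPR points), and the underlying `pROC::roc` object.
#' @export
roc_auc <- function(scores, truth, ci = FALSE) {
  stopifnot(length(scores) == length(truth), all(truth %in% 0:1))
  if (length(unique(truth)) < 2L) stop("both classes must be present")
  r <- pROC::roc(response = truth, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci_v <- NULL
  if (ci) {
    v <- pROC::ci.auc(r, method = "delong")
    ci_v <- c(lower = v[1], upper = v[3])
  }
  list(auc = as.numeric(pROC::auc(r)), ci = ci_v,
       curve = data.frame(fpr = rev(1 - r$specificities),
                          tpr = rev(r$sensitivities)),
       roc = r)
}

#' Compare two score sets on the same samples (paired DeLong test)
#'
#' @param scores_full,scores_clinical two score vectors over the same samples.
#' @param truth 0/1 cancer status.
#' @return list with `auc_full`, `auc_clinical`, `delta`, `p` (two-sided).
#' @export
compare_models <- function(scores_full, scores_clinical, truth) {
  if (length(scores_full) != length(scores_clinical) ||
      length(scores_full) != length(truth))
    stop("score vectors and truth must cover the same samples")
  a1 <- roc_auc(scores_full, truth)
  a2 <- roc_auc(scores_clinical, truth)
  p <- if (isTRUE(all.equal(as.numeric(scores_full),
                            as.numeric(scores_clinical)))) 1
  else pROC::roc.test(a1$roc, a2$roc, method = "delong", paired = TRUE)$p.value
  list(auc_full = a1$auc, auc_clinical = a2$auc,
       delta = a1$auc - a2$auc, p = as.numeric(p))
}

#' Clinical-factors-only comparator model
#'
#' Logistic regression of cancer status on the reported (not genomic)
#' covariates: age, sex, smoking status and pack-years.
#'
#' @param d an `airway_dataset`.
#' @return fitted probabilities, one per sample.
#' @export
clinical_model_scores <- function(d) {
  stopifnot(is_airway_dataset(d))
  ph <- d$phenotypes
  fit <- stats::glm(cancer_status ~ age + sex + smoking_status + pack_years,
                    family = stats::binomial(), data = ph)
  unname(stats::fitted(fit))
}

#' Cross-validation harness for the full derivation
#'
#' For each repetition, holds out a stratified fraction of samples, runs the
#' entire derivation (CFGCs, baseline, gene selection, clustering, reduction,
#' cluster subset, final fit) on the remainder only, and scores the holdout
#' with the derived model — no selection step ever sees holdout samples.
#'
#' @param d an `airway_dataset`.
#' @param config a [derive_config()] used inside every fold.
#' @param holdout holdout fraction (default 0.10).
#' @param reps repetitions.
#' @param seed fold seed.
#' @return list with `rep_auc` (per-repetition holdout AUC), `pooled_auc`
#'   (AUC of all holdout scores pooled), `folds` (held-out sample ids per
#'   repetition), `train_ids` (training sample ids per repetition).
#' @export
cv_harness <- function(d, config = derive_config(), holdout = 0.10, reps = 10,
                       seed = 1) {
  stopifnot(is_airway_dataset(d))
  y <- d$phenotypes$cancer_status
  ids <- d$phenotypes$sample_id
  set.seed(seed)
  folds <- replicate(reps, stratified_holdout(y, holdout), simplify = FALSE)
  all_scores <- numeric(0); all_truth <- integer(0)
  rep_auc <- numeric(reps)
  train_ids <- vector("list", reps)
  for (i in seq_len(reps)) {
    test <- folds[[i]]
    train <- setdiff(seq_along(y), test)
    train_ids[[i]] <- ids[train]
    model <- suppressWarnings(derive_classifier(subset_samples(d, train), config))
    s <- predict(model, subset_samples(d, test), type = "score")
    rep_auc[i] <- roc_auc(s, y[test])$auc
    all_scores <- c(all_scores, s)
    all_truth <- c(all_truth, y[test])
  }
  list(rep_auc = rep_auc,
       pooled_auc = roc_auc(all_scores, all_truth)$auc,
       folds = lapply(folds, function(ix) ids[ix]),
       train_ids = train_ids)
}

#' Published cohort count tables
#'
#' The training-cohort contingency tables (sex, smoking status, mass location
#' by diagnosis) and the test-set detection counts, as packaged fixtures for
#' reproducing the reported exact tests and sensitivity arithmetic.
#'
#' @return nested list of labelled count tables.
#' @export
cohort_tables <- function() {
  path <- system.file("extdata", "cohort_tables.json",
                      package = "airwayclassifier", mustWork = TRUE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("sex", "smoking_status", "mass_location")) {
    m <- doc[[nm]]$counts
    if (is.list(m)) m <- do.call(rbind, lapply(m, unlist))
    dimnames(m) <- list(doc[[nm]]$rows, doc[[nm]]$cols)
    doc[[nm]]$counts <- m
  }
  doc
}

#' Reproduce the reported cohort statistics
#'
#' Recomputes, from the packaged count tables: Fisher exact p-values for sex,
#' smoking status and mass location versus diagnosis in the training cohort,
#' and the test-set detection sensitivities (bronchoscopy alone, classifier
#' among non-diagnostic cancers, combined) with Wilson intervals.
#'
#' @return list with `fisher_p` (named p-values) and `sensitivity` (list of
#'   `confusion`-style proportions with CIs).
#' @export
reproduce_cohort_stats <- function() {
  tab <- cohort_tables()
  fisher_p <- c(sex = fisher_exact(tab$sex$counts),
                smoking_status = fisher_exact(tab$smoking_status$counts),
                mass_location = fisher_exact(tab$mass_location$counts))
  det <- tab$test_set_detection
  sens <- list(
    bronchoscopy = wilson_ci(det$bronchoscopy_detected, det$cancers),
    classifier_nondiagnostic = wilson_ci(det$classifier_detected,
                                         det$nondiagnostic_cancers),
    combined = wilson_ci(det$bronchoscopy_detected + det$classifier_detected,
                         det$cancers))
  list(fisher_p = fisher_p, sensitivity = sens)
}
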