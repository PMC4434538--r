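#' @title Fitting the final classifier
#' @description The final model is a logistic regression over
#'   `age, GG, GS, GPY` and the cluster means, penalized differentially: the
#'   covariates carry no penalty and each cluster mean a ridge penalty of 10.
#'   The penalty is a squared (L2) term `sum_j lambda_j * beta_j^2` on
#'   coefficients of standardized features, added to the summed negative
#'   log-likelihood; coefficients are back-transformed to the raw feature
#'   scale. Fitting is exact Newton-Raphson, so a zero penalty reproduces the
#'   maximum-likelihood fit.
#' @name final-fit
NULL

#' Logistic regression with per-feature ridge penalties
#'
#' Minimizes `-loglik(beta) + sum_j lambda_j * beta_j^2`, with the penalty
#' applied to coefficients of centered/scaled features (the intercept is never
#' penalized) and the returned coefficients back-transformed to the raw scale.
#'
#' @param x numeric matrix (samples x features) with column names.
#' @param y 0/1 response.
#' @param penalty per-feature penalty lambda_j >= 0, recycled if scalar.
#' @param max_iter,tol Newton-Raphson controls.
#' @return list with `intercept`, `coefficients` (named, raw scale),
#'   `fitted`, `converged`, `iterations`.
#' @export
fit_penalized_logistic <- function(x, y, penalty = 0, max_iter = 100,
                                   tol = 1e-10) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(x) == length(y))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  p <- ncol(x)
  penalty <- rep_len(penalty, p)
  if (any(penalty < 0)) stop("penalties must be non-negative")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0))
    stop("constant feature(s): ",
         paste(colnames(x)[scl == 0], collapse = ", "))
  xs <- cbind(`(Intercept)` = 1, sweep(sweep(x, 2, ctr), 2, scl, "/"))
  lam <- c(0, penalty)

  beta <- numeric(p + 1)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(xs %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(xs, y - mu)) - 2 * lam * beta
    w <- pmax(mu * (1 - mu), 1e-10)
    hess <- crossprod(xs * w, xs)
    diag(hess) <- diag(hess) + 2 * lam
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(grad)) < tol || max(abs(step)) < 1e-12) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("penalized logistic fit did not converge in %d iterations (max |grad| = %.3g)",
                    max_iter, max(abs(grad))))
  bs <- beta[-1] / scl
  b0 <- beta[1] - sum(beta[-1] * ctr / scl)
  list(intercept = unname(b0),
       coefficients = stats::setNames(unname(bs), colnames(x)),
       fitted = stats::plogis(drop(cbind(1, x) %*% c(b0, bs))),
       converged = converged, iterations = it)
}

#' Fit the final differentially penalized classifier
#'
#' @param features data.frame of classifier features (columns `age`, `GG`,
#'   `GS`, `GPY` and `CA<k>` cluster means).
#' @param status 0/1 cancer status.
#' @param penalty_covariates ridge penalty on `age/GG/GS/GPY` (default 0).
#' @param penalty_clusters ridge penalty on each cluster mean (default 10).
#' @return as [fit_penalized_logistic()].
#' @export
fit_final <- function(features, status, penalty_covariates = 0,
                      penalty_clusters = 10) {
  features <- as.data.frame(features)
  penalty <- ifelse(grepl("^CA", names(features)), penalty_clusters,
                    penalty_covariates)
  fit_penalized_logistic(as.matrix(features), status, penalty = penalty)
}

#' Choose the decision threshold for a target sensitivity
#'
#' Returns the largest threshold whose sensitivity within the stated subgroup
#' (intended use: patients with a non-diagnostic bronchoscopy) is at least the
#' target. If even the minimum score misses the target, that minimum is
#' returned with a warning.
#'
#' @param scores classifier scores.
#' @param status 0/1 cancer status.
#' @param target_sensitivity target (default 0.90).
#' @param subgroup optional logical mask restricting the evaluation subgroup.
#' @return threshold value.
#' @export
choose_threshold <- function(scores, status, target_sensitivity = 0.90,
                             subgroup = NULL) {
  if (!is.null(subgroup)) { scores <- scores[subgroup]; status <- status[subgroup] }
  pos <- scores[status == 1]
  if (!length(pos) || length(pos) == length(scores))
    stop("threshold subgroup must contain both classes")
  cand <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(cand, function(th) mean(pos >= th), numeric(1))
  ok <- which(sens >= target_sensitivity)
  if (!length(ok)) {
    warning("target sensitivity unattainable; returning the minimum score")
    return(min(scores))
  }
  cand[ok[1]]
}

#' Derivation configuration
#'
#' Defaults are the published procedure's settings: gene selection at
#' p < 0.001, cancer selection at |T| > 2.7, 11 clusters, 2-4 representative
#' genes per cluster at correlation target 0.95, repeated 10% stratified
#' holdout CV, penalties 0 (covariates) / 10 (cluster means), and a decision
#' threshold targeting ~90% sensitivity in the non-diagnostic-bronchoscopy
#' subgroup.
#'
#' @param p_cut CFGC gene selection p cutoff.
#' @param t_cut cancer gene |T| cutoff.
#' @param n_clusters cluster count for the correlation clustering.
#' @param k_max,r_target cluster reduction controls.
#' @param holdout,cv_reps cross-validation controls for cluster-subset
#'   selection.
#' @param penalty_covariates,penalty_clusters final-fit penalties.
#' @param target_sensitivity threshold-setting target.
#' @param cfgc_genes named integer vector of sub-model gene-count targets.
#' @param seed seed for CV folds.
#' @return a `derive_config` list.
#' @export
derive_config <- function(p_cut = 0.001, t_cut = 2.7, n_clusters = 11,
                          k_max = 4, r_target = 0.95, holdout = 0.10,
                          cv_reps = 100, penalty_covariates = 0,
                          penalty_clusters = 10, target_sensitivity = 0.90,
                          cfgc_genes = c(sex = 1, smoking_status = 3,
                                         pack_years = 2),
                          seed = 1) {
  structure(as.list(environment()), class = "derive_config")
}

#' Derive a classifier from a training cohort
#'
#' Runs the full multi-step procedure: CFGC derivation for sex, smoking and
#' pack-years; covariate-only baseline logistic model; selection of cancer
#' genes from the baseline residuals; correlation clustering; reduction of
#' each cluster to 2-4 representatives; CV selection of the cluster subset;
#' the differentially penalized final fit; and threshold setting. When no gene
#' clears a selection cutoff the top-ranked genes are used instead (with a
#' warning), so the procedure remains well-defined on zero-signal cohorts.
#'
#' @param d an `airway_dataset` (requires cancer status, sex, smoking status,
#'   pack-years and age; the bronchoscopy flag is used for threshold setting
#'   when present).
#' @param config a [derive_config()].
#' @return an `airway_classifier` whose `details` element records the CFGC
#'   fits, selected genes, cluster assignment, representatives, chosen
#'   clusters and CV AUCs.
#' @export
derive_classifier <- function(d, config = derive_config()) {
  stopifnot(is_airway_dataset(d), inherits(config, "derive_config"))
  cfg <- config

  cfgc_fits <- list()
  for (fac in c("sex", "smoking_status", "pack_years")) {
    sel <- select_covariate_genes(d, fac, p_cut = cfg$p_cut)
    cand <- sel$gene
    if (!length(cand)) {
      warning("no genes at p < ", cfg$p_cut, " for ", fac,
              "; using the 10 top-ranked genes")
      mt <- moderated_t(d$expression, factor_coding(d$phenotypes, fac))
      cand <- mt$gene[order(mt$p)][1:10]
    }
    cfgc_fits[[fac]] <- fit_cfgc(d, fac, cand,
                                 n_genes = cfg$cfgc_genes[[fac]],
                                 seed = cfg$seed)
  }
  cfgc <- list(sex = as_cfgc_component(cfgc_fits$sex),
               smoking = as_cfgc_component(cfgc_fits$smoking_status),
               pack_years = as_cfgc_component(cfgc_fits$pack_years))

  covariates <- data.frame(GG = apply_cfgc(cfgc$sex, d$expression),
                           GS = apply_cfgc(cfgc$smoking, d$expression),
                           GPY = apply_cfgc(cfgc$pack_years, d$expression))
  baseline <- fit_baseline(d, covariates)

  cancer <- select_cancer_genes(d, baseline$residuals, t_cut = cfg$t_cut)
  if (nrow(cancer) < 4L) {
    warning("fewer than 4 genes at |T| > ", cfg$t_cut,
            "; using the 6 top-ranked genes")
    mt <- moderated_t(d$expression, baseline$residuals, genes_as = "predictor")
    cancer <- mt[order(-abs(mt$t))[1:6], c("gene", "effect", "t", "p")]
  }
  k <- min(cfg$n_clusters, floor(nrow(cancer) / 2))
  clust <- cluster_genes(d, cancer$gene, n_clusters = k)

  reps <- lapply(split(names(clust$assignment), clust$assignment), function(g) {
    if (length(g) == 1L) list(genes = g, correlation = 1)
    else reduce_cluster(d, g, k_max = cfg$k_max, r_target = cfg$r_target)
  })
  names(reps) <- paste0("CA", names(reps))
  rep_clusters <- lapply(reps, `[[`, "genes")
  cm <- cluster_means(d$expression, rep_clusters)

  subset <- select_cluster_subset(d, cm, covariates, holdout = cfg$holdout,
                                  reps = cfg$cv_reps, seed = cfg$seed)
  chosen <- subset$chosen
  if (!length(chosen)) {
    warning("no cluster improved CV AUC; keeping the single best cluster")
    chosen <- colnames(cm)[1]
  }

  features <- data.frame(age = d$phenotypes$age, covariates,
                         cm[, chosen, drop = FALSE], check.names = FALSE)
  fit <- fit_final(features, d$phenotypes$cancer_status,
                   penalty_covariates = cfg$penalty_covariates,
                   penalty_clusters = cfg$penalty_clusters)

  subgroup <- if ("bronchoscopy_diagnostic" %in% names(d$phenotypes))
    d$phenotypes$bronchoscopy_diagnostic == 0L else NULL
  threshold <- choose_threshold(fit$fitted, d$phenotypes$cancer_status,
                                target_sensitivity = cfg$target_sensitivity,
                                subgroup = subgroup)
  threshold <- min(max(threshold, 1e-6), 1 - 1e-6)

  airway_classifier(
    intercept = fit$intercept,
    coefficients = fit$coefficients,
    cfgc = cfgc,
    clusters = rep_clusters[chosen],
    threshold = threshold,
    reference_means = rowMeans(d$expression),
    details = list(cfgc_fits = cfgc_fits,
                   baseline_coefficients = stats::coef(baseline$fit),
                   cancer_genes = cancer,
                   cluster_assignment = clust$assignment,
                   representatives = reps,
                   chosen_clusters = chosen,
                   cv_auc = subset$cv_auc,
                   baseline_cv_auc = subset$baseline_auc,
                   config = cfg))
}
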