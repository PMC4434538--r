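#' @title Clinical-factor gene-expression correlates (CFGCs)
#' @description Each CFGC is a small gene-expression sub-model standing in for
#'   a reported clinical covariate: genomic gender (GG), genomic smoking
#'   status (GS) and genomic pack-years (GPY). Genes associated with the
#'   factor at p < 0.001 (moderated t) are candidates; a LASSO logistic fit
#'   (penalty by 10-fold cross-validated deviance) picks a small set, which is
#'   refit unpenalized so the final sub-model has a plain logistic form. A
#'   factor separated perfectly by a single gene (the Y-linked RPS4Y1 case for
#'   sex) is reported as a threshold rule instead.
#' @name cfgc
NULL

#' Binary coding of a clinical factor
#'
#' sex: female = 1; smoking_status: current = 1; pack_years: > 10 = 1.
#'
#' @param phenotypes phenotype data.frame.
#' @param factor one of `"sex"`, `"smoking_status"`, `"pack_years"`.
#' @return integer 0/1 vector.
#' @export
factor_coding <- function(phenotypes, factor) {
  switch(factor,
         sex = as.integer(phenotypes$sex == "female"),
         smoking_status = as.integer(phenotypes$smoking_status == "current"),
         pack_years = as.integer(phenotypes$pack_years > 10),
         stop("unknown clinical factor '", factor, "'"))
}

#' Select genes associated with a clinical factor
#'
#' Moderated t-test of each gene's expression against the binary-coded factor;
#' genes with p below the cutoff, ranked by p.
#'
#' @param d an `airway_dataset`.
#' @param factor `"sex"`, `"smoking_status"` or `"pack_years"` (dichotomized
#'   at 10 pack-years).
#' @param p_cut selection cutoff (default 0.001).
#' @return data.frame of selected genes (`gene`, `effect`, `t`, `p`), ranked
#'   by p.
#' @export
select_covariate_genes <- function(d, factor, p_cut = 0.001) {
  stopifnot(is_airway_dataset(d))
  y <- factor_coding(d$phenotypes, factor)
  if (length(unique(y)) < 2L)
    stop("clinical factor '", factor, "' is constant in this cohort")
  mt <- moderated_t(d$expression, y, genes_as = "outcome")
  sel <- mt[mt$p < p_cut, c("gene", "effect", "t", "p")]
  sel[order(sel$p), , drop = FALSE]
}

# does any single candidate gene separate the classes with a gap?
perfect_separator <- function(expression, y, candidates) {
  for (g in candidates) {
    v <- expression[g, ]
    lo1 <- min(v[y == 1]); hi1 <- max(v[y == 1])
    lo0 <- min(v[y == 0]); hi0 <- max(v[y == 0])
    if (hi1 < lo0)
      return(list(gene = g, cutpoint = (hi1 + lo0) / 2, direction = "below"))
    if (hi0 < lo1)
      return(list(gene = g, cutpoint = (hi0 + lo1) / 2, direction = "above"))
  }
  NULL
}

#' Fit a CFGC sub-model
#'
#' L1-penalized logistic regression over the candidate genes with the penalty
#' chosen by 10-fold cross-validated deviance; the surviving genes (capped at
#' `n_genes`, keeping the largest penalized coefficients) are refit by
#' unpenalized logistic regression so the reported sub-model is a plain
#' logistic form. When a single candidate separates the factor perfectly, a
#' threshold rule on the top-ranked such gene is returned instead (AUC 1).
#'
#' @param d an `airway_dataset`.
#' @param factor clinical factor name (see [factor_coding()]).
#' @param candidate_genes character vector of candidate gene symbols, in rank
#'   order (as from [select_covariate_genes()]).
#' @param n_genes target number of genes in the sub-model (published
#'   outcomes: 1 for sex, 3 for smoking, 2 for pack-years).
#' @param seed seed for the cross-validation folds.
#' @return list with `factor`, `type` (`"threshold"` or `"logistic"`), the
#'   sub-model fields of [airway_classifier()]'s `cfgc` entries, `genes`, and
#'   `auc` (training AUC).
#' @export
fit_cfgc <- function(d, factor, candidate_genes, n_genes = 3, seed = 1) {
  stopifnot(is_airway_dataset(d))
  if (!length(candidate_genes)) stop("candidate gene list is empty")
  missing <- setdiff(candidate_genes, rownames(d$expression))
  if (length(missing))
    stop("candidate gene(s) not in expression matrix: ",
         paste(missing, collapse = ", "))
  y <- factor_coding(d$phenotypes, factor)
  if (length(unique(y)) < 2L) stop("factor '", factor, "' is constant")

  ps <- perfect_separator(d$expression, y, candidate_genes)
  if (!is.null(ps))
    return(list(factor = factor, type = "threshold", gene = ps$gene,
                cutpoint = ps$cutpoint, direction = ps$direction,
                genes = ps$gene, auc = 1))

  xs <- t(d$expression[candidate_genes, , drop = FALSE])
  if (length(candidate_genes) == 1L) {
    fit <- stats::glm(y ~ xs, family = stats::binomial())
    genes <- candidate_genes
  } else {
    set.seed(seed)
    cv <- glmnet::cv.glmnet(xs, y, family = "binomial", alpha = 1, nfolds = 10)
    b <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
    genes <- names(b)[b != 0]
    if (!length(genes)) genes <- candidate_genes[1]
    if (length(genes) > n_genes)
      genes <- genes[order(-abs(b[genes]))[seq_len(n_genes)]]
    fit <- suppressWarnings(
      stats::glm(y ~ ., family = stats::binomial(),
                 data = data.frame(y = y, t(d$expression[genes, , drop = FALSE]),
                                   check.names = FALSE)))
  }
  cf <- stats::coef(fit)
  pred <- stats::fitted(fit)
  if (!fit$converged || any(abs(cf[-1]) > 30)) {
    # quasi-separation: the unpenalized MLE diverges, so stabilize the refit
    # with a light ridge penalty to keep the logistic form finite
    xg <- t(d$expression[genes, , drop = FALSE])
    pen <- fit_penalized_logistic(xg, y, penalty = 1)
    cf <- c(pen$intercept, pen$coefficients)
    pred <- pen$fitted
  }
  auc <- unname(roc_auc(pred, y)$auc)
  list(factor = factor, type = "logistic", intercept = unname(cf[1]),
       coefficients = stats::setNames(unname(cf[-1]), genes),
       genes = genes, auc = auc)
}

# strip fitting by-products down to the cfgc entry an airway_classifier stores
as_cfgc_component <- function(m) {
  if (m$type == "threshold")
    list(type = "threshold", gene = m$gene, cutpoint = m$cutpoint,
         direction = m$direction)
  else
    list(type = "logistic", intercept = m$intercept,
         coefficients = m$coefficients)
}
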