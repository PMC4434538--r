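#' @title Applying a classifier: CFGC values, cluster means, scores, calls
#' @description The locked scorer is pure arithmetic on the model definition:
#'   genomic gender is a threshold rule on RPS4Y1, genomic smoking and genomic
#'   pack-years are fixed logistic forms, each CA feature is the arithmetic
#'   mean of its member genes' log2 expression, and the score is the logistic
#'   of the linear predictor over `age, GG, GS, GPY, CA*`.
#' @name scoring
NULL

#' Genomic gender from RPS4Y1 expression
#'
#' `GG = 1` (female) iff RPS4Y1 log2 expression is strictly below the
#' cutpoint (7.5 in the published model), else 0 (male).
#'
#' @param rps4y1 numeric vector of RPS4Y1 log2 expression values.
#' @param cutpoint decision boundary (default 7.5).
#' @return integer vector of 0/1.
#' @export
genomic_gender <- function(rps4y1, cutpoint = 7.5) {
  if (any(!is.finite(rps4y1))) stop("RPS4Y1 expression must be finite")
  as.integer(rps4y1 < cutpoint)
}

#' Genomic smoking status
#'
#' Logistic of the published linear form
#' `x = 40.8579 - 0.4462*SLC7A11 - 2.1298*CLDN10 - 1.8256*TKT`.
#'
#' @param slc7a11,cldn10,tkt log2 expression values (vectors of equal length).
#' @return numeric vector in (0,1); values near 1 indicate current smoking.
#' @export
genomic_smoking <- function(slc7a11, cldn10, tkt) {
  if (any(!is.finite(c(slc7a11, cldn10, tkt))))
    stop("SLC7A11/CLDN10/TKT expression must be finite")
  stats::plogis(40.8579 - 0.4462 * slc7a11 - 2.1298 * cldn10 - 1.8256 * tkt)
}

#' Genomic pack-years
#'
#' Logistic of the published linear form
#' `x = -5.1429 + 2.1891*RUNX1T1 - 0.9506*AKR1C2`.
#'
#' @param runx1t1,akr1c2 log2 expression values (vectors of equal length).
#' @return numeric vector in (0,1); values near 1 indicate > 10 pack-years.
#' @export
genomic_pack_years <- function(runx1t1, akr1c2) {
  if (any(!is.finite(c(runx1t1, akr1c2))))
    stop("RUNX1T1/AKR1C2 expression must be finite")
  stats::plogis(-5.1429 + 2.1891 * runx1t1 - 0.9506 * akr1c2)
}

expr_row <- function(expression, gene) {
  if (!gene %in% rownames(expression))
    stop("required gene '", gene, "' missing from expression matrix")
  expression[gene, ]
}

#' Evaluate one CFGC sub-model on an expression matrix
#'
#' @param m a CFGC sub-model (threshold rule or logistic form, see
#'   [airway_classifier()]).
#' @param expression expression matrix (genes x samples).
#' @return numeric vector, one value per sample.
#' @export
apply_cfgc <- function(m, expression) {
  if (m$type == "threshold") {
    v <- expr_row(expression, m$gene)
    if (m$direction == "below") as.numeric(v < m$cutpoint)
    else as.numeric(v > m$cutpoint)
  } else {
    x <- rep(m$intercept, ncol(expression))
    for (g in names(m$coefficients))
      x <- x + m$coefficients[[g]] * expr_row(expression, g)
    stats::plogis(unname(x))
  }
}

#' Per-sample cluster mean expression
#'
#' @param expression expression matrix (genes x samples).
#' @param clusters named list of gene symbol vectors.
#' @return samples x clusters numeric matrix of arithmetic means of the member
#'   genes' log2 expression.
#' @export
cluster_means <- function(expression, clusters) {
  out <- vapply(clusters, function(genes) {
    missing <- setdiff(genes, rownames(expression))
    if (length(missing))
      stop("cluster member gene(s) missing from expression matrix: ",
           paste(missing, collapse = ", "),
           " (use impute_missing_genes() first)")
    colMeans(expression[genes, , drop = FALSE])
  }, numeric(ncol(expression)))
  if (ncol(expression) == 1L) out <- matrix(out, nrow = 1L,
                                            dimnames = list(colnames(expression),
                                                            names(clusters)))
  out
}

#' Build the classifier's feature table for a cohort
#'
#' @param model an `airway_classifier`.
#' @param expression expression matrix covering [classifier_genes()].
#' @param age numeric vector of patient ages in years, one per sample
#'   (column order of `expression`).
#' @return data.frame of features (rows = samples) with the columns named in
#'   `model$coefficients`.
#' @export
classifier_features <- function(model, expression, age) {
  validate_expression(expression)
  if (length(age) != ncol(expression))
    stop("age must have one value per expression sample")
  if (any(!is.finite(age)) || any(age <= 0)) stop("age must be positive and finite")
  fv <- data.frame(age = as.numeric(age),
                   GG = apply_cfgc(model$cfgc$sex, expression),
                   GS = apply_cfgc(model$cfgc$smoking, expression),
                   GPY = apply_cfgc(model$cfgc$pack_years, expression),
                   row.names = colnames(expression))
  cm <- cluster_means(expression, model$clusters)
  fv[colnames(cm)] <- cm
  fv[names(model$coefficients)]
}

#' Score feature vectors with a classifier
#'
#' @param model an `airway_classifier`.
#' @param features data.frame or matrix with the columns named in
#'   `model$coefficients` (as from [classifier_features()]).
#' @return numeric vector of scores in (0,1).
#' @export
classifier_score <- function(model, features) {
  features <- as.data.frame(features)
  missing <- setdiff(names(model$coefficients), names(features))
  if (length(missing))
    stop("feature(s) missing: ", paste(missing, collapse = ", "))
  x <- as.matrix(features[names(model$coefficients)])
  if (any(!is.finite(x))) stop("features must be finite")
  y <- model$intercept + drop(x %*% model$coefficients)
  stats::plogis(unname(y))
}

#' Dichotomize scores
#'
#' @param score numeric scores in `[0,1]`.
#' @param threshold decision threshold; calls are cancer-positive when
#'   `score >= threshold` (boundary inclusive).
#' @return integer vector, 1 = cancer-positive, 0 = cancer-negative.
#' @export
classify <- function(score, threshold = 0.65) {
  if (any(score < 0 | score > 1, na.rm = TRUE)) stop("scores must lie in [0,1]")
  as.integer(score >= threshold)
}

#' Predict method for airway_classifier
#'
#' @param object an `airway_classifier`.
#' @param newdata an `airway_dataset`, or a list with elements `expression`
#'   (matrix) and `age` (numeric per sample).
#' @param type `"score"` (default), `"class"`, or `"features"`.
#' @param ... unused.
#' @return scores, 0/1 calls, or the feature data.frame.
#' @export
predict.airway_classifier <- function(object, newdata,
                                      type = c("score", "class", "features"),
                                      ...) {
  type <- match.arg(type)
  if (is_airway_dataset(newdata)) {
    expression <- newdata$expression
    age <- newdata$phenotypes$age
  } else {
    expression <- newdata$expression
    age <- newdata$age
  }
  fv <- classifier_features(object, expression, age)
  if (type == "features") return(fv)
  s <- classifier_score(object, fv)
  names(s) <- rownames(fv)
  if (type == "score") s else classify(s, object$threshold)
}
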