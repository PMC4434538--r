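#' @title Cross-platform adjustment
#' @description Validating a locked classifier on a cohort measured on a
#'   different microarray platform uses two adjustments: every shared gene is
#'   shifted by a gene-wise constant so its test-cohort mean equals the
#'   training-cohort mean, and classifier genes with no probeset on the new
#'   platform are imputed as constant rows at their training means.
#' @name cross-platform
NULL

#' Training-set reference means
#'
#' @param x an `airway_dataset` or expression matrix of the training cohort.
#' @param provenance short free-text tag recorded with the reference.
#' @return list with `means` (named per-gene vector), `n_samples`,
#'   `provenance`.
#' @export
reference_means <- function(x, provenance = "training cohort") {
  if (is_airway_dataset(x)) x <- x$expression
  validate_expression(x)
  list(means = rowMeans(x), n_samples = ncol(x), provenance = provenance)
}

as_ref_means <- function(ref) {
  m <- if (is.list(ref) && !is.null(ref$means)) ref$means else ref
  if (is.null(names(m)) || any(!is.finite(m)))
    stop("reference means must be a named, finite vector (or reference_means() result)")
  m
}

#' Mean-shift a test cohort onto training reference means
#'
#' For each gene shared with the reference, adds the constant
#' `ref mean - test mean` to all samples, so the adjusted per-gene test mean
#' equals the training mean exactly. Genes absent from the reference pass
#' through unchanged with a warning. Within-cohort variance and per-gene
#' sample ranking are untouched (a constant is added).
#'
#' @param test expression matrix of the test cohort (>= 2 samples).
#' @param ref reference as from [reference_means()] or a named mean vector.
#' @return the adjusted expression matrix.
#' @export
mean_shift_adjust <- function(test, ref) {
  validate_expression(test)
  if (ncol(test) < 2L)
    stop("mean-shift adjustment needs >= 2 test samples to estimate gene means")
  m <- as_ref_means(ref)
  shared <- intersect(rownames(test), names(m))
  if (!length(shared))
    stop("no genes shared between test matrix and reference means")
  extra <- setdiff(rownames(test), names(m))
  if (length(extra))
    warning(length(extra), " gene(s) absent from the reference pass through unadjusted")
  shift <- m[shared] - rowMeans(test[shared, , drop = FALSE])
  test[shared, ] <- test[shared, , drop = FALSE] + shift
  test
}

#' Impute missing classifier genes at training means
#'
#' Each required gene absent from the test matrix but present in the reference
#' is added as a constant row equal to its training mean (the published
#' procedure for LYPD2 and RNF150, absent from the validation platform).
#'
#' @param test expression matrix.
#' @param ref reference as for [mean_shift_adjust()].
#' @param required genes the downstream model needs.
#' @return the expression matrix with missing required genes appended.
#' @export
impute_missing_genes <- function(test, ref, required) {
  validate_expression(test)
  m <- as_ref_means(ref)
  required <- canonical_genes(as.character(required))
  missing <- setdiff(required, rownames(test))
  if (!length(missing)) return(test)
  unavailable <- setdiff(missing, names(m))
  if (length(unavailable))
    stop("gene(s) missing from both test matrix and reference: ",
         paste(unavailable, collapse = ", "))
  message("imputing at training means: ", paste(missing, collapse = ", "))
  add <- matrix(rep(m[missing], ncol(test)), nrow = length(missing),
                dimnames = list(missing, colnames(test)))
  rbind(test, add)
}
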