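#' @title The airway_classifier object
#' @description An `airway_classifier` bundles everything needed to score a
#'   sample: the three clinical-factor gene-expression correlates (CFGCs,
#'   giving genomic gender GG, genomic smoking GS and genomic pack-years GPY),
#'   the cancer gene clusters whose per-sample means are the CA features, the
#'   logistic coefficients over `age, GG, GS, GPY, CA*`, and the decision
#'   threshold. The published model ships with the package
#'   ([locked_classifier()]); [derive_classifier()] produces new objects of
#'   the same class from a training cohort.
#' @name classifier-object
NULL

CLASSIFIER_SCHEMA_VERSION <- 1L

#' Construct an airway_classifier
#'
#' @param intercept logistic intercept b0.
#' @param coefficients named numeric vector; names are feature labels
#'   (`age`, `GG`, `GS`, `GPY`, and one `CA<k>` per cancer cluster).
#' @param cfgc list with components `sex`, `smoking`, `pack_years`, each either
#'   a threshold rule (`list(type = "threshold", gene, cutpoint, direction)`)
#'   or a logistic form (`list(type = "logistic", intercept, coefficients)`),
#'   coefficients named by gene.
#' @param clusters named list of gene symbol vectors, names matching the
#'   `CA<k>` coefficient labels.
#' @param threshold decision threshold on the score; calls are positive when
#'   score >= threshold.
#' @param reference_means optional named vector of training-set per-gene mean
#'   expression, used for cross-platform adjustment/imputation; `NULL` when
#'   unavailable.
#' @param details optional list of derivation by-products (selected genes,
#'   cluster assignments, CV performance).
#' @return an object of class `airway_classifier`.
#' @export
airway_classifier <- function(intercept, coefficients, cfgc, clusters,
                              threshold = 0.65, reference_means = NULL,
                              details = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  if (is.null(names(coefficients)) || any(names(coefficients) == ""))
    stop("coefficients must be a fully named numeric vector")
  if (any(!is.finite(coefficients))) stop("coefficients must be finite")
  ca <- grep("^CA", names(coefficients), value = TRUE)
  if (!setequal(ca, names(clusters)))
    stop("cluster names must match the CA coefficient labels")
  for (nm in names(clusters)) {
    clusters[[nm]] <- canonical_genes(as.character(clusters[[nm]]))
    if (!length(clusters[[nm]])) stop("cluster ", nm, " has no member genes")
  }
  for (comp in c("sex", "smoking", "pack_years")) {
    m <- cfgc[[comp]]
    if (is.null(m) || !m$type %in% c("threshold", "logistic"))
      stop("cfgc$", comp, " must be a threshold or logistic sub-model")
    if (m$type == "threshold") {
      cfgc[[comp]]$gene <- canonical_genes(m$gene)
    } else {
      cf <- unlist(m$coefficients)
      names(cf) <- canonical_genes(names(cf))
      cfgc[[comp]]$coefficients <- cf
    }
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0,1)")
  if (!is.null(reference_means)) {
    reference_means <- unlist(reference_means)
    names(reference_means) <- canonical_genes(names(reference_means))
  }
  structure(list(schema_version = CLASSIFIER_SCHEMA_VERSION,
                 intercept = intercept,
                 coefficients = coefficients,
                 cfgc = cfgc,
                 clusters = clusters,
                 threshold = threshold,
                 reference_means = reference_means,
                 details = details),
            class = "airway_classifier")
}

#' Genes required by a classifier
#'
#' @param model an `airway_classifier`.
#' @return character vector of all gene symbols the model reads.
#' @export
classifier_genes <- function(model) {
  cf <- unlist(lapply(model$cfgc, function(m)
    if (m$type == "threshold") m$gene else names(m$coefficients)))
  unique(c(unname(cf), unlist(model$clusters, use.names = FALSE)))
}

#' @export
print.airway_classifier <- function(x, ...) {
  cat("Bronchial airway gene-expression lung-cancer classifier\n")
  cat(sprintf("  %d features, %d genes, decision threshold %.2f\n",
              length(x$coefficients), length(classifier_genes(x)), x$threshold))
  cat("  score = plogis(", format(x$intercept), " + sum(b_i * x_i))\n", sep = "")
  invisible(x)
}

#' @export
coef.airway_classifier <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
summary.airway_classifier <- function(object, ...) {
  print(object)
  df <- data.frame(coefficient = object$coefficients)
  df$genes <- vapply(rownames(df), function(nm) {
    if (nm %in% names(object$clusters))
      paste(object$clusters[[nm]], collapse = ", ")
    else if (nm == "GG" && object$cfgc$sex$type == "threshold")
      object$cfgc$sex$gene
    else if (nm == "GS" && object$cfgc$smoking$type == "logistic")
      paste(names(object$cfgc$smoking$coefficients), collapse = ", ")
    else if (nm == "GPY" && object$cfgc$pack_years$type == "logistic")
      paste(names(object$cfgc$pack_years$coefficients), collapse = ", ")
    else ""
  }, character(1))
  print(df)
  invisible(df)
}

locked_env <- new.env(parent = emptyenv())

#' The published (locked) classifier
#'
#' The finalized 23-gene model: genomic gender (RPS4Y1 threshold), genomic
#' smoking (SLC7A11, CLDN10, TKT), genomic pack-years (RUNX1T1, AKR1C2), six
#' cancer gene cluster means (17 gene measurements), patient age, logistic
#' coefficients, intercept 3.3173 and decision threshold 0.65. Training-set
#' reference means were not published and are marked unavailable; scoring a
#' cohort from another platform therefore needs a user-supplied reference
#' (see [mean_shift_adjust()]).
#'
#' @return an `airway_classifier`.
#' @export
locked_classifier <- function() {
  if (is.null(locked_env$model)) {
    path <- system.file("extdata", "locked_classifier.json",
                        package = "airwayclassifier", mustWork = TRUE)
    locked_env$model <- load_model(path)
  }
  locked_env$model
}
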