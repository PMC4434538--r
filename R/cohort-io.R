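#' @title Expression matrices, phenotype tables and aligned cohorts
#' @description Readers, writers and validators for the two tabular inputs the
#'   pipeline consumes: a genes-by-samples matrix of RMA-normalized log2
#'   intensities (TSV, genes in rows, header row of sample ids) and a
#'   per-sample clinical phenotype table (CSV). An aligned pair is an
#'   `airway_dataset`.
#' @name cohort-io
NULL

required_pheno_cols <- c("sample_id", "cancer_status", "sex", "smoking_status",
                         "pack_years", "age")
optional_pheno_cols <- c("bronchoscopy_diagnostic", "mass_size_class",
                         "mass_location", "histology")

#' Validate an expression matrix
#'
#' @param x numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @return `x`, invisibly, after checking invariants.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene rownames and sample colnames")
  dup_g <- rownames(x)[duplicated(rownames(x))]
  if (length(dup_g))
    stop("duplicate gene ids in expression matrix: ",
         paste(unique(dup_g), collapse = ", "))
  dup_s <- colnames(x)[duplicated(colnames(x))]
  if (length(dup_s))
    stop("duplicate sample ids in expression matrix: ",
         paste(unique(dup_s), collapse = ", "))
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  invisible(x)
}

#' Read a log2 expression matrix
#'
#' Tab-separated text, genes in rows; first column holds gene symbols and the
#' header row holds sample ids. Known symbol aliases are canonicalized
#' (see [gene_aliases()]).
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("expression file '", path, "' has no sample columns in its header")
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = c("character", rep("numeric", length(header) - 1L)),
                          quote = "", comment.char = "")
  genes <- canonical_genes(df[[1]])
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- genes
  storage.mode(x) <- "double"
  validate_expression(x)
  x
}

#' Write a log2 expression matrix
#'
#' @param x expression matrix as from [read_expression()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' CSV with columns `sample_id, cancer_status, sex, smoking_status,
#' pack_years, age` plus optional `bronchoscopy_diagnostic, mass_size_class,
#' mass_location, histology`. Unknown categories in optional fields are kept
#' as `"unknown"`.
#'
#' @param path file path.
#' @return data.frame with typed columns, one row per sample.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_pheno_cols, names(df))
  if (length(missing))
    stop("phenotype file missing required column(s): ",
         paste(missing, collapse = ", "))
  validate_phenotypes(df)
}

#' Validate (and type) a phenotype table
#'
#' @param df data.frame carrying at least the required phenotype columns.
#' @return the typed, validated data.frame.
#' @export
validate_phenotypes <- function(df) {
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in phenotype table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df$cancer_status <- as.integer(df$cancer_status)
  if (any(is.na(df$cancer_status)) || !all(df$cancer_status %in% c(0L, 1L)))
    stop("cancer_status must be 0 or 1 for every sample")
  df$sex <- tolower(as.character(df$sex))
  if (!all(df$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'; offending sample(s): ",
         paste(df$sample_id[!df$sex %in% c("male", "female")], collapse = ", "))
  df$smoking_status <- tolower(as.character(df$smoking_status))
  if (!all(df$smoking_status %in% c("current", "former")))
    stop("smoking_status must be 'current' or 'former'")
  df$pack_years <- suppressWarnings(as.numeric(df$pack_years))
  if (any(is.na(df$pack_years)) || any(df$pack_years < 0))
    stop("pack_years must be a non-negative number for every sample")
  df$age <- suppressWarnings(as.numeric(df$age))
  if (any(is.na(df$age)) || any(df$age <= 0))
    stop("age must be a positive number for every sample")
  if ("bronchoscopy_diagnostic" %in% names(df)) {
    df$bronchoscopy_diagnostic <- as.integer(df$bronchoscopy_diagnostic)
    if (!all(df$bronchoscopy_diagnostic %in% c(0L, 1L), na.rm = TRUE))
      stop("bronchoscopy_diagnostic must be 0/1 where present")
  }
  for (col in c("mass_size_class", "mass_location", "histology")) {
    if (col %in% names(df)) {
      v <- as.character(df[[col]])
      v[is.na(v) | v == ""] <- "unknown"
      df[[col]] <- v
    }
  }
  df
}

#' Write a phenotype table
#'
#' @param df phenotype data.frame.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align an expression matrix with a phenotype table
#'
#' Restricts both to their common samples, in phenotype order, and returns an
#' `airway_dataset`. Samples present on one side only are dropped with a
#' message.
#'
#' @param expression expression matrix.
#' @param phenotypes phenotype data.frame.
#' @return an `airway_dataset`: list with elements `expression` (matrix) and
#'   `phenotypes` (data.frame), sample sets identical and in identical order.
#' @export
align_dataset <- function(expression, phenotypes) {
  validate_expression(expression)
  phenotypes <- validate_phenotypes(phenotypes)
  common <- intersect(phenotypes$sample_id, colnames(expression))
  if (!length(common))
    stop("no samples shared between expression matrix and phenotype table")
  drop_e <- setdiff(colnames(expression), common)
  drop_p <- setdiff(phenotypes$sample_id, common)
  if (length(drop_e) || length(drop_p))
    message(sprintf("align_dataset: dropped %d expression-only and %d phenotype-only sample(s)",
                    length(drop_e), length(drop_p)))
  phenotypes <- phenotypes[match(common, phenotypes$sample_id), , drop = FALSE]
  rownames(phenotypes) <- NULL
  structure(list(expression = expression[, common, drop = FALSE],
                 phenotypes = phenotypes),
            class = "airway_dataset")
}

#' @export
print.airway_dataset <- function(x, ...) {
  n <- ncol(x$expression)
  cat(sprintf("airway_dataset: %d genes x %d samples (%d cancer, %d benign)\n",
              nrow(x$expression), n,
              sum(x$phenotypes$cancer_status == 1L),
              sum(x$phenotypes$cancer_status == 0L)))
  invisible(x)
}

is_airway_dataset <- function(x) inherits(x, "airway_dataset")

#' Subset an airway_dataset by samples
#'
#' @param d an `airway_dataset`.
#' @param samples sample ids or logical/integer index into the current order.
#' @return the restricted `airway_dataset`.
#' @export
subset_samples <- function(d, samples) {
  stopifnot(is_airway_dataset(d))
  if (is.character(samples)) samples <- match(samples, d$phenotypes$sample_id)
  ph <- d$phenotypes[samples, , drop = FALSE]
  rownames(ph) <- NULL
  structure(list(expression = d$expression[, samples, drop = FALSE],
                 phenotypes = ph),
            class = "airway_dataset")
}
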