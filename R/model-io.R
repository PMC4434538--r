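#' Save a classifier to a versioned JSON document
#'
#' @param model an `airway_classifier`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "airway_classifier"))
  cfgc <- lapply(model$cfgc, function(m) {
    if (!is.null(m$coefficients)) m$coefficients <- as.list(m$coefficients)
    m
  })
  doc <- list(schema_version = model$schema_version,
              intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              cfgc = cfgc,
              clusters = model$clusters,
              threshold = model$threshold,
              reference_means = if (is.null(model$reference_means)) NULL
                                else as.list(model$reference_means))
  # digits = I(17): significant digits, enough for exact double round-trip
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a classifier from JSON
#'
#' @param path path to a document written by [save_model()] (or the packaged
#'   locked model).
#' @return an `airway_classifier`.
#' @export
load_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse model file '", path,
                                           "': ", conditionMessage(e)))
  for (field in c("schema_version", "intercept", "coefficients", "cfgc",
                  "clusters", "threshold"))
    if (is.null(doc[[field]]))
      stop("model file '", path, "' lacks required field '", field, "'")
  if (doc$schema_version != CLASSIFIER_SCHEMA_VERSION)
    stop(sprintf("model schema version %s not supported (expected %d)",
                 doc$schema_version, CLASSIFIER_SCHEMA_VERSION))
  cfgc <- lapply(doc$cfgc, function(m) {
    m$coefficients <- if (!is.null(m$coefficients)) unlist(m$coefficients)
    m
  })
  rm_ <- if (!is.null(doc$reference_means)) unlist(doc$reference_means)
  airway_classifier(intercept = doc$intercept,
                    coefficients = unlist(doc$coefficients),
                    cfgc = cfgc,
                    clusters = lapply(doc$clusters, unlist),
                    threshold = doc$threshold,
                    reference_means = rm_)
}
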