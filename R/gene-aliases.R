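#' Gene symbol aliases
#'
#' The published classifier prints two nonstandard claudin symbols (CLND10,
#' CLND22). The package canonicalizes symbols at read/load time so that
#' expression matrices and model definitions agree regardless of which
#' spelling a file uses.
#'
#' @return Named character vector mapping alias -> canonical symbol.
#' @export
gene_aliases <- function() {
  c(CLND10 = "CLDN10", CLND22 = "CLDN22")
}

#' Canonicalize gene symbols
#'
#' @param genes character vector of gene symbols.
#' @return character vector with known aliases replaced by canonical symbols.
#' @export
canonical_genes <- function(genes) {
  al <- gene_aliases()
  hit <- genes %in% names(al)
  genes[hit] <- unname(al[genes[hit]])
  genes
}
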