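# internal helpers shared across the package

# Gene symbol aliases accepted on input and mapped to the canonical symbol.
# PTRPC is a common transposition of PTPRC (CD45) seen in published tables.
.GENE_ALIASES <- c(PTRPC = "PTPRC")

#' Canonicalize gene symbols
#'
#' Upper-cases symbols and maps known aliases (currently `PTRPC -> PTPRC`)
#' to their canonical HGNC form.  All gene matching in the package goes
#' through this function, so expression matrices and marker sets using
#' either spelling interoperate.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of canonical symbols, same length as `x`.
#' @examples
#' canonicalSymbols(c("ptprc", "PTRPC", "Cd8a"))
#' @export
canonicalSymbols <- function(x) {
  x <- toupper(as.character(x))
  hit <- x %in% names(.GENE_ALIASES)
  x[hit] <- .GENE_ALIASES[x[hit]]
  x
}

# geometric mean of strictly positive values
.geomMean <- function(x) exp(mean(log(x)))

# mean of off-diagonal entries of a symmetric matrix (NA-tolerant)
.offDiagMean <- function(m) {
  if (nrow(m) < 2L) return(NA_real_)
  mean(m[upper.tri(m)], na.rm = TRUE)
}

.checkScalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  invisible(x)
}
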