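#' Read an expression matrix from a delimited text file
#'
#' Reads a TSV/CSV gene x sample expression table into a
#' [TILExpression-class] object.  The first column (or the row header) is
#' taken as gene symbols and the header row as sample identifiers.  Gene
#' symbols are upper-cased and known aliases mapped to canonical form so
#' they match the bundled marker set.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter; `NULL` (default) sniffs tab vs comma
#'   from the header line.
#' @param orientation `"genes_by_samples"` (default), `"samples_by_genes"`,
#'   or `"auto"`.  With `"auto"` the table is transposed when the column
#'   names — but not the row names — contain known immune marker symbols.
#' @param scale Scale of the stored values (`"raw_counts"`,
#'   `"linear_normalized"` or `"log2"`).
#' @return A validated [TILExpression-class].
#' @details Duplicate gene or sample identifiers, non-numeric cells (with
#'   their coordinates) and negative values on a count scale are reported
#'   as errors.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write.table(matrix(1:6, 3, dimnames = list(c("CD8A","CD8B","GZMA"),
#'                                            c("s1","s2"))),
#'             tf, sep = "\t", quote = FALSE, col.names = NA)
#' readExpression(tf)
#' @export
readExpression <- function(path, delimiter = NULL,
                           orientation = c("genes_by_samples",
                                           "samples_by_genes", "auto"),
                           scale = c("raw_counts", "linear_normalized",
                                     "log2")) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) {
    hdr <- readLines(path, n = 1L)
    delimiter <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", colClasses = c("character"))
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate gene identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  chr <- as.matrix(df[, -1L, drop = FALSE])
  rownames(chr) <- ids
  m <- suppressWarnings(matrix(as.numeric(chr), nrow(chr),
                               dimnames = dimnames(chr)))
  bad <- which(is.na(m) & !is.na(chr) & toupper(chr) != "NA",
               arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric cell at row '", rownames(m)[bad[1, 1]],
         "', column '", colnames(m)[bad[1, 2]], "'")
  if (orientation == "auto") {
    known <- .bundledGeneSymbols()
    inCols <- mean(canonicalSymbols(colnames(m)) %in% known)
    inRows <- mean(canonicalSymbols(rownames(m)) %in% known)
    if (inCols > inRows) m <- t(m)
  } else if (orientation == "samples_by_genes") {
    m <- t(m)
  }
  for (dim in 1:2) {
    ids <- dimnames(m)[[dim]]
    if (anyDuplicated(ids))
      stop("duplicate ", c("gene", "sample")[dim], " identifiers: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (scale != "log2" && any(m < 0, na.rm = TRUE))
    stop("negative values found but scale = '", scale, "'")
  TILExpression(m, scale = scale, metadata = list(source = path))
}

# symbols of the bundled marker set, used by orientation auto-detection
.bundledGeneSymbols <- function() {
  f <- system.file("extdata", "marker_genes.tsv", package = "TILscore")
  unique(utils::read.delim(f, stringsAsFactors = FALSE)$gene)
}

#' Log2-transform an expression matrix
#'
#' Applies `log2(value + pseudocount)` to a raw-count or linear-scale
#' matrix.  All downstream scoring and similarity statistics operate on
#' the log2 scale, where one unit corresponds to one doubling.
#'
#' @param m A [TILExpression-class] not already on the log2 scale.
#' @param pseudocount Non-negative offset added before taking logs
#'   (default 1, so zero counts map to 0).  Recorded in the object
#'   metadata.
#' @return A [TILExpression-class] with `exprScale == "log2"`.
#' @examples
#' m <- TILExpression(matrix(c(0, 3, 500, 7), 2,
#'        dimnames = list(c("CD8A","CD8B"), c("s1","s2"))))
#' exprValues(log2Transform(m))
#' @export
log2Transform <- function(m, pseudocount = 1) {
  stopifnot(is(m, "TILExpression"))
  if (exprScale(m) == "log2")
    stop("already log scale")
  .checkScalar(pseudocount, "pseudocount")
  if (pseudocount < 0) stop("'pseudocount' must be non-negative")
  v <- exprValues(m)
  if (pseudocount == 0 && any(v == 0))
    stop("zero values with pseudocount 0; log2 undefined")
  md <- S4Vectors::metadata(m)
  md$pseudocount <- pseudocount
  md$previous_scale <- exprScale(m)
  TILExpression(log2(v + pseudocount), scale = "log2", metadata = md)
}
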