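#' Pairwise marker-likeness similarity of two genes
#'
#' Computes the co-expression similarity statistic
#' \deqn{similarity(x, y) = \frac{\sum (x - \bar x)(y - \bar y)}
#'   {\frac{n-1}{2}\,(var(x) + var(y))}
#'   = \frac{2\,cov(x, y)}{var(x) + var(y)},}
#' where `x` and `y` are log2-transformed, normalized expression vectors
#' and the variances are unbiased (divisor n - 1).  The statistic equals 1
#' only when the two genes are perfectly correlated with slope 1 — the
#' pattern expected of two ideal markers of the same cell type — and is
#' penalized both by imperfect correlation and by slopes away from 1
#' (for an exact linear relation with slope b and unit predictor variance
#' it equals 2b / (1 + b^2)).  By the AM-GM inequality
#' |similarity| <= |Pearson r|, with equality iff var(x) = var(y).
#'
#' @param x,y Numeric vectors of equal length (n >= 3), each with positive
#'   sample variance.
#' @return A number in \[-1, 1\].
#' @examples
#' pairwiseSimilarity(c(1, 2, 3), c(3, 4, 5))   # slope 1 -> 1
#' pairwiseSimilarity(c(1, 2, 3), c(2, 4, 6))   # slope 2 -> 0.8
#' @export
pairwiseSimilarity <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3L) stop("at least 3 samples are required")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 || vy == 0) stop("degenerate gene: zero sample variance")
  sum((x - mean(x)) * (y - mean(y))) / (((n - 1) / 2) * (vx + vy))
}

#' Pairwise similarity matrix over a gene set
#'
#' Computes [pairwiseSimilarity()] between all pairs of the requested
#' genes in a log2 expression matrix, alongside the Pearson correlation
#' matrix for diagnostics.  Genes absent from the data are recorded, not
#' fabricated; zero-variance genes are dropped with a warning.
#'
#' @param m A log2-scale [TILExpression-class], or a plain numeric matrix
#'   of log2 values (genes x samples).
#' @param genes Gene symbols to analyze; default all genes in `m`.
#' @param datasetLabel Provenance label stored in the result.
#' @param ... Passed between methods.
#' @return A [SimilarityResult-class].
#' @export
setGeneric("similarityMatrix",
           function(m, genes = NULL, datasetLabel = "dataset", ...)
             standardGeneric("similarityMatrix"))

#' @rdname similarityMatrix
#' @export
setMethod("similarityMatrix", "TILExpression",
  function(m, genes = NULL, datasetLabel = "dataset", ...) {
    if (exprScale(m) != "log2")
      stop("similarity requires log2-scale data; run log2Transform() first")
    similarityMatrix(exprValues(m), genes = genes,
                     datasetLabel = datasetLabel, ...)
  })

#' @rdname similarityMatrix
#' @export
setMethod("similarityMatrix", "matrix",
  function(m, genes = NULL, datasetLabel = "dataset", ...) {
    if (is.null(genes)) genes <- rownames(m)
    genes <- unique(canonicalSymbols(genes))
    present <- intersect(genes, rownames(m))
    absent <- setdiff(genes, present)
    x <- m[present, , drop = FALSE]
    v <- apply(x, 1L, stats::var)
    dropped <- present[v == 0]
    if (length(dropped)) {
      warning("dropping zero-variance gene(s): ",
              paste(dropped, collapse = ", "))
      x <- x[v > 0, , drop = FALSE]
    }
    usable <- rownames(x)
    if (length(usable) < 2L)
      stop("fewer than 2 usable genes for similarity computation")
    C <- stats::cov(t(x))
    d <- diag(C)
    sim <- 2 * C / outer(d, d, `+`)
    rho <- stats::cov2cor(C)
    new("SimilarityResult", genes = usable, similarity = sim,
        correlation = rho, nSamples = ncol(x),
        datasetLabel = datasetLabel, absentGenes = absent,
        droppedGenes = dropped,
        pairCounts = matrix(1L, nrow(sim), ncol(sim),
                            dimnames = dimnames(sim)))
  })

#' Average similarity matrices across datasets
#'
#' Combines per-dataset [SimilarityResult-class] objects into one matrix
#' in which each gene pair's similarity is the unweighted mean over the
#' datasets where both genes were present (each dataset counts equally
#' regardless of its sample size).  Pairs observed in no dataset are `NA`;
#' the per-pair contribution counts are kept so users can filter on them.
#'
#' @param matrices List of [SimilarityResult-class] objects over the same
#'   candidate gene universe (gene coverage may differ per dataset).
#' @return A [SimilarityResult-class] over the union of genes.
#' @export
averageSimilarity <- function(matrices) {
  if (!length(matrices)) stop("at least one similarity matrix is required")
  if (!all(vapply(matrices, is, logical(1), "SimilarityResult")))
    stop("all inputs must be SimilarityResult objects")
  genes <- unique(unlist(lapply(matrices, function(x) x@genes)))
  k <- length(genes)
  simSum <- corSum <- matrix(0, k, k, dimnames = list(genes, genes))
  counts <- matrix(0L, k, k, dimnames = list(genes, genes))
  for (mres in matrices) {
    g <- mres@genes
    simSum[g, g] <- simSum[g, g] + mres@similarity
    corSum[g, g] <- corSum[g, g] + mres@correlation
    counts[g, g] <- counts[g, g] + mres@pairCounts
  }
  sim <- ifelse(counts > 0, simSum / counts, NA_real_)
  rho <- ifelse(counts > 0, corSum / counts, NA_real_)
  dimnames(sim) <- dimnames(rho) <- list(genes, genes)
  absent <- setdiff(unique(unlist(lapply(matrices,
                                         function(x) x@absentGenes))),
                    genes)
  new("SimilarityResult", genes = genes, similarity = sim,
      correlation = rho,
      nSamples = sum(vapply(matrices, function(x) x@nSamples, integer(1))),
      datasetLabel = paste0("average of ", length(matrices), " dataset(s)"),
      absentGenes = absent,
      droppedGenes = unique(unlist(lapply(matrices,
                                          function(x) x@droppedGenes))),
      pairCounts = counts)
}

#' Clustered heatmap of a similarity matrix
#'
#' Draws the standard marker-QC heatmap: genes clustered by average
#' linkage on 1 - similarity, cells colored by similarity value.
#'
#' @param x A [SimilarityResult-class].
#' @param file Optional path (`.png` or `.pdf`) to write the figure to.
#' @param ... Passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
similarityHeatmap <- function(x, file = NULL, ...) {
  stopifnot(is(x, "SimilarityResult"))
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("package 'pheatmap' is required for heatmaps")
  s <- x@similarity
  s[is.na(s)] <- 0
  d <- stats::as.dist(1 - s)
  hc <- stats::hclust(d, method = "average")
  p <- pheatmap::pheatmap(x@similarity, cluster_rows = hc,
                          cluster_cols = hc, breaks = seq(-1, 1, 0.02),
                          main = x@datasetLabel, silent = !is.null(file),
                          filename = if (is.null(file)) NA else file, ...)
  invisible(p)
}
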