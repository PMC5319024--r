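#' Select stable reference genes (geNorm)
#'
#' Ranks candidate reference genes by the geNorm stability measure M and
#' iteratively removes the least stable gene down to `minGenes`.  For gene
#' j, M_j is the mean, over all other candidates k, of the standard
#' deviation across samples of `log2(x_j / x_k)`: a gene whose expression
#' keeps a constant ratio to every other reference gene has M = 0.
#'
#' @param m A [TILExpression-class] on a raw-count or linear scale.
#' @param candidates Candidate reference gene symbols.
#' @param minGenes Minimum panel size retained (default 3); the full
#'   exclusion trajectory is recorded so any larger cut can be recovered.
#' @return A [ReferencePanel-class] with the retained subset, the initial
#'   stability values, and the exclusion order.
#' @details Candidates absent from the matrix or containing a zero (or
#'   negative) count are excluded up front with a warning, since their
#'   log ratios are undefined.  Fewer than `minGenes` usable candidates is
#'   an error.  M is invariant to rescaling any sample's whole profile,
#'   which is what makes it a content-independent stability measure.
#' @seealso [referenceNormalize()]
#' @export
selectReferenceGenes <- function(m, candidates, minGenes = 3L) {
  stopifnot(is(m, "TILExpression"))
  if (exprScale(m) == "log2")
    stop("geNorm operates on count-scale data, not log2")
  minGenes <- as.integer(minGenes)
  if (minGenes < 2L) stop("'minGenes' must be at least 2")
  candidates <- canonicalSymbols(candidates)
  if (anyDuplicated(candidates))
    candidates <- unique(candidates)
  v <- exprValues(m)
  absent <- setdiff(candidates, rownames(v))
  present <- setdiff(candidates, absent)
  nonpos <- present[apply(v[present, , drop = FALSE] <= 0, 1L, any)]
  usable <- setdiff(present, nonpos)
  excluded <- c(absent, nonpos)
  if (length(absent))
    warning("candidates absent from data: ", paste(absent, collapse = ", "))
  if (length(nonpos))
    warning("candidates with non-positive counts excluded: ",
            paste(nonpos, collapse = ", "))
  if (length(usable) < minGenes)
    stop("fewer than ", minGenes, " usable candidate reference genes")

  lx <- log2(v[usable, , drop = FALSE])
  Mvals <- function(genes) {
    sapply(genes, function(j) {
      others <- setdiff(genes, j)
      mean(sapply(others, function(k) stats::sd(lx[j, ] - lx[k, ])))
    })
  }
  stability <- Mvals(usable)

  kept <- usable
  steps <- list()
  while (length(kept) > minGenes) {
    M <- Mvals(kept)
    worst <- names(M)[order(-M, names(M))][1L]
    steps[[length(steps) + 1L]] <-
      data.frame(step = length(steps) + 1L, removed_gene = worst,
                 M_at_removal = unname(M[worst]),
                 stringsAsFactors = FALSE)
    kept <- setdiff(kept, worst)
  }
  trajectory <- if (length(steps)) do.call(rbind, steps) else
    data.frame(step = integer(), removed_gene = character(),
               M_at_removal = numeric())
  new("ReferencePanel", candidates = candidates, selected = kept,
      stability = stability, trajectory = trajectory, excluded = excluded)
}

#' Normalize an expression matrix to reference genes
#'
#' Divides each sample's profile by the geometric mean of its reference
#' genes, then multiplies all samples by the grand geometric mean of those
#' per-sample factors, returning values to an intelligible count space.
#' After normalization every sample has the same reference-gene geometric
#' mean, so the operation is idempotent.
#'
#' @param m A [TILExpression-class] on a raw-count or linear scale.
#' @param panel A [ReferencePanel-class] (or character vector of reference
#'   gene symbols).
#' @return A [TILExpression-class] with `exprScale == "linear_normalized"`.
#' @examples
#' v <- rbind(REF1 = c(1, 16), REF2 = c(4, 4), GENE = c(10, 10))
#' colnames(v) <- c("s1", "s2")   # reference geometric means 2 and 8
#' m <- TILExpression(v)
#' exprValues(referenceNormalize(m, c("REF1", "REF2")))["GENE", ]
#' @export
referenceNormalize <- function(m, panel) {
  stopifnot(is(m, "TILExpression"))
  if (exprScale(m) == "log2")
    stop("reference normalization operates on count-scale data, not log2")
  refs <- if (is(panel, "ReferencePanel")) selectedReferences(panel)
          else canonicalSymbols(panel)
  v <- exprValues(m)
  missing <- setdiff(refs, rownames(v))
  if (length(missing))
    stop("reference genes absent from data: ",
         paste(missing, collapse = ", "))
  rv <- v[refs, , drop = FALSE]
  zero <- which(rv <= 0, arr.ind = TRUE)
  if (nrow(zero))
    stop("non-positive reference count for gene '",
         refs[zero[1, 1]], "' in sample '", colnames(v)[zero[1, 2]], "'")
  f <- apply(rv, 2L, .geomMean)
  G <- .geomMean(f)
  out <- sweep(v, 2L, G / f, `*`)
  md <- S4Vectors::metadata(m)
  md$reference_genes <- refs
  md$normalization_factor <- G / f
  TILExpression(out, scale = "linear_normalized", metadata = md)
}
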