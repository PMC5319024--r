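#' @rdname TILExpression-class
#' @export
setMethod("exprScale", "TILExpression", function(x) x@exprScale)

#' @rdname TILExpression-class
#' @export
setMethod("exprValues", "TILExpression",
          function(x) SummarizedExperiment::assay(x, "exprs"))

#' @rdname TILExpression-class
#' @export
setMethod("geneIds", "TILExpression", function(x) rownames(x))

#' @rdname TILExpression-class
#' @export
setMethod("sampleIds", "TILExpression", function(x) colnames(x))

setMethod("show", "TILExpression", function(object) {
  cat("TILExpression:", nrow(object), "genes x", ncol(object),
      "samples, scale =", object@exprScale, "\n")
  if (length(S4Vectors::metadata(object)))
    cat("  metadata:", paste(names(S4Vectors::metadata(object)),
                             collapse = ", "), "\n")
})

#' @rdname MarkerSet-class
#' @param cellType Optional cell type name; when given, returns that cell
#'   type's gene vector instead of the full list.
#' @export
setMethod("markerGenes", "MarkerSet", function(x, cellType = NULL) {
  if (is.null(cellType)) return(x@markers)
  if (!cellType %in% names(x@markers))
    stop("unknown cell type '", cellType, "'")
  x@markers[[cellType]]
})

#' @rdname MarkerSet-class
#' @export
setMethod("cellTypes", "MarkerSet", function(x) names(x@markers))

#' @rdname MarkerSet-class
#' @export
setMethod("derivedScores", "MarkerSet", function(x) x@derived)

setMethod("show", "MarkerSet", function(object) {
  ng <- sum(lengths(object@markers))
  cat("MarkerSet:", length(object@markers), "cell types,", ng, "genes")
  if (length(object@derived))
    cat(";", length(object@derived), "derived score(s):",
        paste(names(object@derived), collapse = ", "))
  cat("\n")
  for (ct in names(object@markers)) {
    g <- object@markers[[ct]]
    cat("  ", format(ct, width = 18), length(g), "gene(s): ",
        paste(utils::head(g, 6), collapse = ", "),
        if (length(g) > 6) ", ..." else "", "\n", sep = "")
  }
})

#' @rdname ReferencePanel-class
#' @export
setMethod("selectedReferences", "ReferencePanel", function(x) x@selected)

#' @rdname ReferencePanel-class
#' @export
setMethod("stabilityValues", "ReferencePanel", function(x) x@stability)

#' @rdname ReferencePanel-class
#' @export
setMethod("exclusionTrajectory", "ReferencePanel", function(x) x@trajectory)

setMethod("show", "ReferencePanel", function(object) {
  cat("ReferencePanel:", length(object@selected), "of",
      length(object@candidates), "candidates selected\n")
  cat("  selected:", paste(object@selected, collapse = ", "), "\n")
  if (length(object@excluded))
    cat("  excluded (invalid counts):",
        paste(object@excluded, collapse = ", "), "\n")
})

#' @rdname SimilarityResult-class
#' @export
setMethod("similarityValues", "SimilarityResult", function(x) x@similarity)

#' @rdname SimilarityResult-class
#' @export
setMethod("correlationValues", "SimilarityResult", function(x) x@correlation)

#' @rdname SimilarityResult-class
#' @export
setMethod("pairCounts", "SimilarityResult", function(x) x@pairCounts)

setMethod("show", "SimilarityResult", function(object) {
  cat("SimilarityResult [", object@datasetLabel, "]: ",
      length(object@genes), " genes, n = ", object@nSamples,
      " samples\n", sep = "")
  if (length(object@genes) >= 2)
    cat("  mean off-diagonal similarity:",
        round(.offDiagMean(object@similarity), 3), "\n")
  if (length(object@absentGenes))
    cat("  absent from data:", paste(object@absentGenes, collapse = ", "),
        "\n")
  if (length(object@droppedGenes))
    cat("  dropped (zero variance):",
        paste(object@droppedGenes, collapse = ", "), "\n")
})

#' @rdname MarkerSelection-class
#' @export
setMethod("selectedMarkers", "MarkerSelection", function(x) x@selected)

#' @rdname MarkerSelection-class
#' @export
setMethod("selectionTable", "MarkerSelection", function(x) {
  rbind(
    if (length(x@selected))
      data.frame(cell_type = x@cellType, gene = x@selected,
                 outcome = "selected", reason = NA_character_),
    if (nrow(x@discarded))
      data.frame(cell_type = x@cellType, gene = x@discarded$gene,
                 outcome = "discarded", reason = x@discarded$reason)
  )
})

setMethod("show", "MarkerSelection", function(object) {
  cat("MarkerSelection [", object@cellType, "]: ",
      length(object@selected), "/", length(object@candidates),
      " candidates selected; status = ", object@status, "\n", sep = "")
  if (length(object@selected))
    cat("  selected:", paste(object@selected, collapse = ", "), "\n")
  if (!is.na(object@meanSimilarity))
    cat("  mean pairwise similarity:",
        round(object@meanSimilarity, 3), "\n")
  if (nrow(object@discarded))
    for (r in split(object@discarded$gene, object@discarded$reason))
      cat("  discarded (", object@discarded$reason[
            match(r[1], object@discarded$gene)], "): ",
          paste(r, collapse = ", "), "\n", sep = "")
})

#' @rdname CellScores-class
#' @export
setMethod("scoreMatrix", "CellScores", function(x) x@scores)

#' @rdname CellScores-class
#' @export
setMethod("tilsScore", "CellScores", function(x) {
  if (!length(x@totalTILs)) stop("Total TILs not computed; run totalTILs()")
  x@totalTILs
})

#' @rdname CellScores-class
#' @export
setMethod("tilsInclusion", "CellScores", function(x) x@tilsInfo)

#' @rdname CellScores-class
#' @export
setMethod("enrichmentMatrix", "CellScores", function(x) {
  if (!nrow(x@enrichment))
    stop("enrichment scores not computed; run enrichmentScores()")
  x@enrichment
})

#' @rdname CellScores-class
#' @export
setMethod("scoreProvenance", "CellScores", function(x) x@provenance)

setMethod("show", "CellScores", function(object) {
  cat("CellScores:", nrow(object@scores), "samples x",
      ncol(object@scores), "cell types (", object@scoreType, ")\n")
  cat("  cell types:", paste(colnames(object@scores), collapse = ", "),
      "\n")
  if (length(object@totalTILs)) cat("  Total TILs: computed\n")
  if (nrow(object@enrichment)) cat("  enrichment scores: computed\n")
})

#' @rdname VarianceComponents-class
#' @export
setMethod("noiseProportion", "VarianceComponents",
          function(x) x@noiseProportion)

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents (", object@nSamples, " samples, ",
      paste(range(object@nReplicates), collapse = "-"),
      " replicates):\n", sep = "")
  cat(sprintf("  between-sample variance: %.4g\n", object@betweenVar))
  cat(sprintf("  residual variance:       %.4g (SD %.4g, log2 scale)\n",
              object@residVar, object@residSD))
  cat(sprintf("  proportion of variance due to noise: %.4g\n",
              object@noiseProportion))
  if (object@truncated)
    cat("  note: between-sample component at zero boundary\n")
})

#' @rdname TILSimulation-class
#' @export
setMethod("trueAbundance", "TILSimulation", function(x) x@trueAbundance)

#' @rdname TILSimulation-class
#' @export
setMethod("geneRoles", "TILSimulation", function(x) x@geneRoles)

#' @rdname TILSimulation-class
#' @export
setMethod("simExpression", "TILSimulation", function(x) x@expression)

setMethod("show", "TILSimulation", function(object) {
  cat("TILSimulation:", ncol(object@expression), "samples,",
      nrow(object@expression), "genes,",
      ncol(object@trueAbundance), "latent cell type(s); seed =",
      object@config@seed, "\n")
})
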