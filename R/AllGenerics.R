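#' @rdname TILExpression-class
#' @param x,object An object.
#' @param ... Additional arguments (unused).
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' @rdname TILExpression-class
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname TILExpression-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname TILExpression-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname MarkerSet-class
#' @param x,object An object.
#' @export
setGeneric("markerGenes", function(x, ...) standardGeneric("markerGenes"))

#' @rdname MarkerSet-class
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname MarkerSet-class
#' @export
setGeneric("derivedScores", function(x) standardGeneric("derivedScores"))

#' @rdname ReferencePanel-class
#' @param x,object An object.
#' @export
setGeneric("selectedReferences",
           function(x) standardGeneric("selectedReferences"))

#' @rdname ReferencePanel-class
#' @export
setGeneric("stabilityValues", function(x) standardGeneric("stabilityValues"))

#' @rdname ReferencePanel-class
#' @export
setGeneric("exclusionTrajectory",
           function(x) standardGeneric("exclusionTrajectory"))

#' @rdname SimilarityResult-class
#' @param x,object An object.
#' @export
setGeneric("similarityValues",
           function(x) standardGeneric("similarityValues"))

#' @rdname SimilarityResult-class
#' @export
setGeneric("correlationValues",
           function(x) standardGeneric("correlationValues"))

#' @rdname SimilarityResult-class
#' @export
setGeneric("pairCounts", function(x) standardGeneric("pairCounts"))

#' @rdname MarkerSelection-class
#' @param x,object An object.
#' @export
setGeneric("selectedMarkers", function(x) standardGeneric("selectedMarkers"))

#' @rdname MarkerSelection-class
#' @export
setGeneric("selectionTable", function(x) standardGeneric("selectionTable"))

#' @rdname CellScores-class
#' @param x,object An object.
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname CellScores-class
#' @export
setGeneric("tilsScore", function(x) standardGeneric("tilsScore"))

#' @rdname CellScores-class
#' @export
setGeneric("tilsInclusion", function(x) standardGeneric("tilsInclusion"))

#' @rdname CellScores-class
#' @export
setGeneric("enrichmentMatrix", function(x) standardGeneric("enrichmentMatrix"))

#' @rdname CellScores-class
#' @export
setGeneric("scoreProvenance", function(x) standardGeneric("scoreProvenance"))

#' @rdname VarianceComponents-class
#' @param x,object An object.
#' @export
setGeneric("noiseProportion", function(x) standardGeneric("noiseProportion"))

#' @rdname TILSimulation-class
#' @param x,object An object.
#' @export
setGeneric("trueAbundance", function(x) standardGeneric("trueAbundance"))

#' @rdname TILSimulation-class
#' @export
setGeneric("geneRoles", function(x) standardGeneric("geneRoles"))

#' @rdname TILSimulation-class
#' @export
setGeneric("simExpression", function(x) standardGeneric("simExpression"))
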