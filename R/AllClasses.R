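#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom S4Vectors metadata metadata<-
NULL

.EXPR_SCALES <- c("raw_counts", "linear_normalized", "log2")

#' TILExpression: an expression matrix with an explicit scale
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' a single `exprs` assay (genes in rows, samples in columns) plus a flag
#' recording whether values are raw counts, normalized linear-scale values,
#' or log2-transformed.  Downstream operations check the flag: similarity
#' and scoring require `log2`, reference-gene normalization requires a
#' positive linear scale.
#'
#' @slot exprScale One of `"raw_counts"`, `"linear_normalized"`, `"log2"`.
#'
#' @seealso [readExpression()], [log2Transform()], [referenceNormalize()]
#' @export
setClass("TILExpression",
  contains = "SummarizedExperiment",
  representation(exprScale = "character")
)

setValidity("TILExpression", function(object) {
  msg <- character()
  if (length(object@exprScale) != 1L || !object@exprScale %in% .EXPR_SCALES)
    msg <- c(msg, paste0("exprScale must be one of: ",
                         paste(.EXPR_SCALES, collapse = ", ")))
  g <- rownames(object); s <- colnames(object)
  if (is.null(g) || is.null(s))
    msg <- c(msg, "gene (row) and sample (column) names are required")
  if (!is.null(g) && anyDuplicated(g))
    msg <- c(msg, paste0("duplicate gene identifiers: ",
                         paste(unique(g[duplicated(g)]), collapse = ", ")))
  if (!is.null(s) && anyDuplicated(s))
    msg <- c(msg, paste0("duplicate sample identifiers: ",
                         paste(unique(s[duplicated(s)]), collapse = ", ")))
  v <- SummarizedExperiment::assay(object, "exprs")
  if (!is.numeric(v))
    msg <- c(msg, "expression values must be numeric")
  if (length(object@exprScale) == 1L && object@exprScale != "log2" &&
      is.numeric(v) && any(v < 0, na.rm = TRUE))
    msg <- c(msg, paste0("negative values are not allowed on scale '",
                         object@exprScale, "'"))
  if (length(msg)) msg else TRUE
})

#' Construct a TILExpression object
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols,
#'   colnames = sample identifiers).
#' @param scale Scale of the values; one of `"raw_counts"`,
#'   `"linear_normalized"`, `"log2"`.
#' @param metadata Optional named list stored in the object metadata
#'   (e.g. provenance of a normalization step).
#' @return A [TILExpression-class] object.  Gene symbols are upper-cased
#'   and known aliases mapped to canonical form.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(c("CD8A","CD8B","GZMA"),
#'                                            c("s1","s2")))
#' TILExpression(m, scale = "raw_counts")
#' @export
TILExpression <- function(values,
                          scale = c("raw_counts", "linear_normalized", "log2"),
                          metadata = list()) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have rownames (genes) and colnames (samples)")
  rownames(values) <- canonicalSymbols(rownames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values))
  S4Vectors::metadata(se) <- metadata
  new("TILExpression", se, exprScale = scale)
}

#' MarkerSet: cell types and their marker genes
#'
#' Maps each cell population to an ordered list of marker gene symbols.
#' Cell types measured by a single gene are flagged as such (their quality
#' cannot be assessed from co-expression alone).  Derived scores are
#' contrasts of two scored cell types computed after scoring, e.g. a CD4
#' cell score defined as the T-cell score minus the CD8 T-cell score.
#'
#' @slot markers Named list, cell type -> character vector of gene symbols.
#' @slot singleGene Named logical, `TRUE` for single-gene cell types.
#' @slot derived Named list of derived scores; each element is
#'   `list(from = <cell type>, minus = <cell type>)`.
#' @slot info `data.frame` of per-cell-type annotations (candidate counts,
#'   reference mean pairwise similarity, free-text notes).
#' @export
setClass("MarkerSet",
  representation(markers = "list", singleGene = "logical",
                 derived = "list", info = "data.frame")
)

setValidity("MarkerSet", function(object) {
  msg <- character()
  if (is.null(names(object@markers)) || any(!nzchar(names(object@markers))))
    msg <- c(msg, "all cell types must be named")
  for (ct in names(object@markers)) {
    g <- object@markers[[ct]]
    if (!is.character(g) || length(g) < 1L)
      msg <- c(msg, paste0("cell type '", ct, "' has no marker genes"))
    else if (anyDuplicated(g))
      msg <- c(msg, paste0("cell type '", ct, "' lists duplicate genes: ",
                           paste(unique(g[duplicated(g)]), collapse = ", ")))
  }
  for (d in names(object@derived)) {
    el <- object@derived[[d]]
    if (!is.list(el) || !all(c("from", "minus") %in% names(el)))
      msg <- c(msg, paste0("derived score '", d,
                           "' must be list(from=, minus=)"))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MarkerSet-class Constructor.
#' @param markers Named list, cell type -> character vector of gene symbols.
#' @param singleGene Optional named logical; defaults to `lengths(markers) == 1`.
#' @param derived Named list of derived-score definitions
#'   (`list(from =, minus =)`).
#' @param info Optional per-cell-type annotation `data.frame`.
#' @export
MarkerSet <- function(markers, singleGene = NULL, derived = list(),
                      info = data.frame()) {
  markers <- lapply(markers, canonicalSymbols)
  if (is.null(singleGene)) singleGene <- lengths(markers) == 1L
  new("MarkerSet", markers = markers,
      singleGene = singleGene, derived = derived, info = info)
}

#' ReferencePanel: geNorm reference-gene selection result
#'
#' @slot candidates Candidate reference gene symbols supplied.
#' @slot selected Retained reference genes (most stable subset).
#' @slot stability Named numeric, initial stability M per usable candidate
#'   (mean SD of pairwise log2 ratios across samples; lower = more stable).
#' @slot trajectory `data.frame` of the full exclusion order: one row per
#'   removal step with the removed gene and its M at removal.
#' @slot excluded Candidates dropped before ranking (zero counts or absent).
#' @seealso [selectReferenceGenes()], [referenceNormalize()]
#' @export
setClass("ReferencePanel",
  representation(candidates = "character", selected = "character",
                 stability = "numeric", trajectory = "data.frame",
                 excluded = "character")
)

setValidity("ReferencePanel", function(object) {
  msg <- character()
  if (!all(object@selected %in% object@candidates))
    msg <- c(msg, "selected genes must be a subset of candidates")
  if (length(object@selected) < 2L)
    msg <- c(msg, "at least 2 reference genes must be selected")
  if (length(msg)) msg else TRUE
})

#' SimilarityResult: pairwise marker-likeness of a gene set
#'
#' Symmetric gene x gene matrix of the pairwise similarity statistic
#' (2*cov / (var + var) on log2 expression), together with the plain
#' Pearson correlation matrix for diagnostics (|similarity| <= |r| always,
#' with equality only at equal variances).  For cross-dataset averages the
#' `pairCounts` slot records how many datasets contributed to each pair.
#'
#' @slot genes Ordered gene symbols covered by the matrix.
#' @slot similarity Symmetric numeric matrix in \[-1, 1\]; diagonal 1.
#' @slot correlation Pearson correlation matrix over the same genes.
#' @slot nSamples Number of samples the statistics were computed from
#'   (sum over datasets for averages).
#' @slot datasetLabel Free-text provenance label.
#' @slot absentGenes Requested genes missing from the expression data.
#' @slot droppedGenes Genes dropped for zero variance.
#' @slot pairCounts Integer matrix of contributing-dataset counts.
#' @export
setClass("SimilarityResult",
  representation(genes = "character", similarity = "matrix",
                 correlation = "matrix", nSamples = "integer",
                 datasetLabel = "character", absentGenes = "character",
                 droppedGenes = "character", pairCounts = "matrix")
)

setValidity("SimilarityResult", function(object) {
  msg <- character()
  s <- object@similarity
  if (nrow(s) != length(object@genes) || ncol(s) != length(object@genes))
    msg <- c(msg, "similarity matrix dimensions must match genes")
  if (nrow(s) && max(abs(s - t(s)), na.rm = TRUE) > 1e-8)
    msg <- c(msg, "similarity matrix must be symmetric")
  if (nrow(s) && any(abs(s) > 1 + 1e-8, na.rm = TRUE))
    msg <- c(msg, "similarity values must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' MarkerSelection: outcome of marker selection for one cell type
#'
#' @slot cellType Cell type name.
#' @slot candidates Candidate genes submitted.
#' @slot selected Genes retained as markers.
#' @slot discarded `data.frame(gene, reason)` for every candidate not
#'   selected; reasons are `low_similarity`, `non_unit_slope_cluster`,
#'   `domain_exclusion`, `absent_from_data`.
#' @slot meanSimilarity Mean off-diagonal pairwise similarity of the
#'   selected genes (`NA` when fewer than 2 selected).
#' @slot status One of `accepted`, `discarded_low_similarity`,
#'   `single_gene_unvalidated`.
#' @slot meanExpression Mean log2 expression of the selected genes
#'   (diagnostic; `NA` until [cellTypeQuality()] attaches it).
#' @export
setClass("MarkerSelection",
  representation(cellType = "character", candidates = "character",
                 selected = "character", discarded = "data.frame",
                 meanSimilarity = "numeric", status = "character",
                 meanExpression = "numeric")
)

setValidity("MarkerSelection", function(object) {
  msg <- character()
  ok <- c("low_similarity", "non_unit_slope_cluster",
          "domain_exclusion", "absent_from_data")
  if (nrow(object@discarded) &&
      !all(object@discarded$reason %in% ok))
    msg <- c(msg, "unknown discard reason")
  covered <- sort(c(object@selected, object@discarded$gene))
  if (!identical(covered, sort(object@candidates)))
    msg <- c(msg, "selected + discarded must partition the candidates")
  if (length(msg)) msg else TRUE
})

#' CellScores: per-sample cell type abundance scores
#'
#' Samples x cell types matrix of log2-scale scores (one unit = one
#' doubling of inferred abundance, up to an unknown per-cell-type
#' constant), with optional Total TILs and enrichment columns.
#'
#' @slot scores Numeric matrix, samples x cell types.
#' @slot totalTILs Per-sample Total TILs score (length 0 until computed).
#' @slot tilsInfo List describing the Total TILs inclusion rule outcome
#'   (included/excluded cell types, correlations, threshold, method).
#' @slot enrichment Samples x cell types matrix of enrichment scores
#'   (residuals of each score regressed on Total TILs; 0 x 0 until
#'   computed).
#' @slot provenance Named list, cell type -> marker genes actually used
#'   (or derived-score formula).
#' @slot scoreType `"log2"` for plain scores, `"anchored:<cell type>"`
#'   after [normalizeToCellType()], `"baseline_relative"` after
#'   [relativeToBaseline()].
#' @export
setClass("CellScores",
  representation(scores = "matrix", totalTILs = "numeric",
                 tilsInfo = "list", enrichment = "matrix",
                 provenance = "list", scoreType = "character")
)

setValidity("CellScores", function(object) {
  msg <- character()
  if (is.null(rownames(object@scores)) || is.null(colnames(object@scores)))
    msg <- c(msg, "score matrix needs sample rownames and cell type colnames")
  if (length(object@totalTILs) &&
      length(object@totalTILs) != nrow(object@scores))
    msg <- c(msg, "totalTILs length must equal the number of samples")
  if (length(msg)) msg else TRUE
})

#' VarianceComponents: replicate reproducibility decomposition
#'
#' One-way random-effects decomposition of replicate cell scores into
#' between-sample and residual (technical) variance, both in squared log2
#' units.  The noise proportion is residual / (residual + between).
#'
#' @slot betweenVar Between-sample variance estimate.
#' @slot residVar Residual (technical) variance estimate.
#' @slot noiseProportion residVar / (residVar + betweenVar); 0 by
#'   convention when all values are identical.
#' @slot residSD Residual SD on the log2 scale.
#' @slot nSamples Number of distinct samples.
#' @slot nReplicates Replicate count per sample.
#' @slot truncated `TRUE` when the between-sample component was truncated
#'   at the zero boundary.
#' @export
setClass("VarianceComponents",
  representation(betweenVar = "numeric", residVar = "numeric",
                 noiseProportion = "numeric", residSD = "numeric",
                 nSamples = "integer", nReplicates = "integer",
                 truncated = "logical")
)

setValidity("VarianceComponents", function(object) {
  msg <- character()
  if (object@betweenVar < 0 || object@residVar < 0)
    msg <- c(msg, "variance components must be non-negative")
  if (!is.na(object@noiseProportion) &&
      (object@noiseProportion < 0 || object@noiseProportion > 1))
    msg <- c(msg, "noiseProportion must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the synthetic expression generator
#'
#' @slot nSamples Number of samples to simulate.
#' @slot cellTypes `data.frame(name, log2_mean, log2_sd)` of latent
#'   cell-type abundances on the log2 scale.
#' @slot genes `data.frame(symbol, role, cell_type, constant, noise_sd,
#'   gamma)`; `role` is one of `pure`, `contaminant`, `slope`, `noise`;
#'   `cell_type` may list several types separated by `";"` for
#'   contaminants; `constant` is the linear-scale expression constant
#'   (copies per cell); `gamma` is the slope for `slope` genes.
#' @slot infiltrateLoading Loading of the shared "total infiltrate"
#'   latent factor on every cell type's abundance (0 = independent cell
#'   types).
#' @slot seed RNG seed (mandatory).
#' @seealso [simConfig()], [simulateDataset()]
#' @export
setClass("SimulationConfig",
  representation(nSamples = "integer", cellTypes = "data.frame",
                 genes = "data.frame", infiltrateLoading = "numeric",
                 seed = "integer")
)

#' TILSimulation: synthetic dataset with known ground truth
#'
#' @slot expression Simulated log2 [TILExpression-class] matrix.
#' @slot trueAbundance Samples x cell types matrix of latent log2
#'   abundances.
#' @slot geneRoles `data.frame` mapping each gene to its generating role.
#' @slot config The [SimulationConfig-class] used.
#' @export
setClass("TILSimulation",
  representation(expression = "TILExpression", trueAbundance = "matrix",
                 geneRoles = "data.frame", config = "SimulationConfig")
)
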