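#' Run the marker-gene QC workflow over one or more datasets
#'
#' Orchestrates the full candidate-gene triage for one cell type:
#' per-dataset similarity matrices, cross-dataset averaging, clustering-
#' based selection, and the final quality verdict.
#'
#' @param datasets A log2 [TILExpression-class] or a (optionally named)
#'   list of them.
#' @param candidates Candidate marker gene symbols (non-empty).
#' @param cellType Cell type name for the report.
#' @param highThreshold,moderateThreshold,exclusions,discardThreshold
#'   Passed to [selectMarkers()] and [cellTypeQuality()].
#' @param outDir Optional directory; when given, the averaged similarity
#'   matrix and the selection table are written there as TSV (and a
#'   clustered heatmap as PNG when `pheatmap` is available).
#' @return A list with `perDataset` (similarity per dataset), `average`,
#'   `report` (a [MarkerSelection-class] after quality triage), and
#'   `quality` (a one-row summary mirroring the columns of a marker-set
#'   quality table: candidates, selected, mean pairwise similarity,
#'   status).
#' @export
runQC <- function(datasets, candidates, cellType = "cell type",
                  highThreshold = 0.6, moderateThreshold = 0.4,
                  exclusions = character(), discardThreshold = 0.4,
                  outDir = NULL) {
  if (is(datasets, "TILExpression")) datasets <- list(datasets)
  if (!length(datasets)) stop("at least one expression dataset is required")
  if (!length(candidates)) stop("candidate gene list is empty")
  labels <- names(datasets)
  if (is.null(labels)) labels <- paste0("dataset_", seq_along(datasets))
  per <- mapply(function(d, lbl)
    similarityMatrix(d, genes = candidates, datasetLabel = lbl),
    datasets, labels, SIMPLIFY = FALSE)
  avg <- averageSimilarity(per)
  rep <- selectMarkers(avg, candidates = candidates,
                       highThreshold = highThreshold,
                       moderateThreshold = moderateThreshold,
                       exclusions = exclusions, cellType = cellType)
  rep <- cellTypeQuality(list(rep), discardThreshold = discardThreshold,
                         expr = datasets[[1L]])[[1L]]
  quality <- data.frame(cell_type = cellType,
                        n_candidates = length(rep@candidates),
                        n_selected = length(rep@selected),
                        mean_pairwise_similarity = rep@meanSimilarity,
                        status = rep@status,
                        stringsAsFactors = FALSE)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(similarityValues(avg),
                       file.path(outDir, "similarity_average.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(selectionTable(rep),
                       file.path(outDir, "selection_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(quality, file.path(outDir, "quality_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (requireNamespace("pheatmap", quietly = TRUE) &&
        length(avg@genes) >= 2L)
      try(similarityHeatmap(avg,
                            file = file.path(outDir, "similarity.png")),
          silent = TRUE)
  }
  list(perDataset = per, average = avg, report = rep, quality = quality)
}

#' Run the scoring workflow
#'
#' Computes cell scores from an expression matrix and a marker set, with
#' optional Total TILs, enrichment, anchoring and baseline-relative
#' reporting, and optionally writes the results as TSV.
#'
#' @param expr A log2 [TILExpression-class] (raw-count input is
#'   log2-transformed automatically with `pseudocount`).
#' @param markers A [MarkerSet-class] (default the bundled set).
#' @param tils Compute the Total TILs score (default `TRUE`; requires a
#'   CD45 score or `cd45`).
#' @param enrichment Compute enrichment scores (default `TRUE`; implies
#'   `tils`).
#' @param cd45,tilsThreshold Passed to [totalTILs()].
#' @param anchor Optional cell type to anchor scores to
#'   ([normalizeToCellType()]).
#' @param baselineIds Optional baseline sample set
#'   ([relativeToBaseline()]).
#' @param pseudocount Pseudocount for automatic log2 transformation.
#' @param outDir Optional output directory for `cell_scores.tsv` (scores
#'   plus Total TILs and enrichment columns) and `provenance.tsv`.
#' @return A [CellScores-class].
#' @export
runScore <- function(expr, markers = bundledMarkerSet(), tils = TRUE,
                     enrichment = TRUE, cd45 = NULL, tilsThreshold = 0.6,
                     anchor = NULL, baselineIds = NULL, pseudocount = 1,
                     outDir = NULL) {
  stopifnot(is(expr, "TILExpression"))
  if (exprScale(expr) != "log2")
    expr <- log2Transform(expr, pseudocount = pseudocount)
  sc <- cellScores(expr, markers)
  if (tils || enrichment)
    sc <- totalTILs(sc, cd45 = cd45, threshold = tilsThreshold)
  if (enrichment) sc <- enrichmentScores(sc)
  if (!is.null(anchor)) sc <- normalizeToCellType(sc, anchor)
  if (!is.null(baselineIds)) sc <- relativeToBaseline(sc, baselineIds)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    out <- as.data.frame(scoreMatrix(sc))
    if (length(sc@totalTILs)) out$Total.TILs <- sc@totalTILs
    if (nrow(sc@enrichment)) {
      enr <- as.data.frame(sc@enrichment)
      names(enr) <- paste0("enrichment.", names(enr))
      out <- cbind(out, enr)
    }
    utils::write.table(out, file.path(outDir, "cell_scores.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    prov <- data.frame(
      cell_type = names(scoreProvenance(sc)),
      genes_used = vapply(scoreProvenance(sc), paste,
                          character(1), collapse = ","),
      stringsAsFactors = FALSE)
    utils::write.table(prov, file.path(outDir, "provenance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sc
}
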