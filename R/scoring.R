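#' Compute cell type abundance scores
#'
#' Scores each cell type as the arithmetic mean of its marker genes' log2
#' expression per sample.  Under the model that each marker is present at
#' a fixed (unknown) number of copies per cell, this mean equals the log2
#' abundance of the cell type plus an unknown constant, so one score unit
#' corresponds to one doubling of abundance; scores of different cell
#' types are not comparable without calibration.  Derived scores defined
#' in the marker set (e.g. CD4 cells = T-cells minus CD8 T cells) are
#' computed afterwards from the scored columns.
#'
#' @param m A log2-scale [TILExpression-class].
#' @param markers A [MarkerSet-class] (default [bundledMarkerSet()]).
#' @param allowMissing When `TRUE` (default), a cell type is scored from
#'   whichever of its markers are present in `m` (the practical rule for
#'   panels that carry only a subset of the genes); cell types with no
#'   marker present are skipped with a warning.  When `FALSE`, any
#'   missing marker is an error.
#' @return A [CellScores-class]; the provenance slot lists the genes
#'   actually averaged for each cell type.
#' @examples
#' v <- rbind(CD8A = c(4, 2), CD8B = c(6, 4))
#' colnames(v) <- c("s1", "s2")
#' m <- TILExpression(v, scale = "log2")
#' ms <- MarkerSet(list("CD8 T cells" = c("CD8A", "CD8B")))
#' scoreMatrix(cellScores(m, ms))
#' @export
cellScores <- function(m, markers = bundledMarkerSet(),
                       allowMissing = TRUE) {
  stopifnot(is(m, "TILExpression"), is(markers, "MarkerSet"))
  if (exprScale(m) != "log2")
    stop("scoring requires log2-scale data; run log2Transform() first")
  v <- exprValues(m)
  cols <- list(); prov <- list()
  for (ct in cellTypes(markers)) {
    g <- unique(markerGenes(markers, ct))
    have <- intersect(g, rownames(v))
    if (length(have) < length(g) && !allowMissing)
      stop("cell type '", ct, "' is missing marker(s): ",
           paste(setdiff(g, have), collapse = ", "))
    if (!length(have)) {
      warning("cell type '", ct, "' has no marker genes in the data; ",
              "skipped")
      next
    }
    cols[[ct]] <- colMeans(v[have, , drop = FALSE])
    prov[[ct]] <- have
  }
  if (!length(cols)) stop("no cell type could be scored")
  scores <- do.call(cbind, cols)
  rownames(scores) <- colnames(v)
  for (d in names(derivedScores(markers))) {
    def <- derivedScores(markers)[[d]]
    if (all(c(def$from, def$minus) %in% colnames(scores))) {
      scores <- cbind(scores, scores[, def$from] - scores[, def$minus])
      colnames(scores)[ncol(scores)] <- d
      prov[[d]] <- paste0("derived: ", def$from, " - ", def$minus)
    } else {
      warning("derived score '", d, "' skipped: requires scores for '",
              def$from, "' and '", def$minus, "'")
    }
  }
  new("CellScores", scores = scores, totalTILs = numeric(),
      tilsInfo = list(), enrichment = matrix(numeric(), 0, 0),
      provenance = prov, scoreType = "log2")
}

#' Total TILs composite score
#'
#' The cell scores of most immune populations rise and fall together with
#' the overall amount of infiltrate.  The Total TILs score captures this
#' shared axis: it is the per-sample mean of all cell scores whose
#' correlation with CD45 (PTPRC) expression exceeds `threshold`.  The
#' inclusion set is recomputed on the data at hand (different cohorts
#' legitimately exclude different cell types); pass `include` to freeze
#' it for reproduction.
#'
#' @param scores A [CellScores-class].
#' @param cd45 Per-sample log2 CD45 (PTPRC) expression aligned to the
#'   score rows.  Defaults to the `"CD45"` score column when present.
#' @param threshold Correlation cutoff (default 0.6; strictly greater
#'   includes).
#' @param method Correlation type, `"pearson"` (default) or
#'   `"spearman"`.
#' @param include Optional character vector of cell types to average,
#'   bypassing the correlation rule.
#' @return The [CellScores-class] with the Total TILs slot filled and the
#'   inclusion report in `tilsInclusion()`.
#' @export
totalTILs <- function(scores, cd45 = NULL, threshold = 0.6,
                      method = c("pearson", "spearman"), include = NULL) {
  stopifnot(is(scores, "CellScores"))
  method <- match.arg(method)
  sm <- scores@scores
  if (nrow(sm) < 2L) stop("at least 2 samples are required")
  if (is.null(cd45)) {
    if (!"CD45" %in% colnames(sm))
      stop("no 'cd45' vector given and no CD45 score column present")
    cd45 <- sm[, "CD45"]
  }
  if (length(cd45) != nrow(sm))
    stop("'cd45' must align with the score rows (",
         nrow(sm), " samples)")
  cors <- apply(sm, 2L, stats::cor, y = cd45, method = method)
  if (is.null(include)) {
    include <- colnames(sm)[!is.na(cors) & cors > threshold]
    if (!length(include))
      stop("no cell score has correlation with CD45 above ", threshold,
           "; review the threshold or the data")
  } else {
    missing <- setdiff(include, colnames(sm))
    if (length(missing))
      stop("'include' names unscored cell types: ",
           paste(missing, collapse = ", "))
  }
  scores@totalTILs <-
    rowMeans(sm[, include, drop = FALSE])
  names(scores@totalTILs) <- rownames(sm)
  scores@tilsInfo <- list(included = include,
                          excluded = setdiff(colnames(sm), include),
                          correlations = cors, threshold = threshold,
                          method = method)
  scores
}

#' Cell type enrichment scores
#'
#' Regresses each cell score on the Total TILs score (ordinary least
#' squares with intercept, fit on the supplied samples) and keeps the
#' residuals.  An enrichment score measures a cell type's abundance
#' relative to what the overall infiltrate level predicts: an enrichment
#' of 1 means the sample has twice as many of that cell type as the
#' average sample with the same Total TILs.
#'
#' @param scores A [CellScores-class] with Total TILs computed.
#' @return The [CellScores-class] with the enrichment slot filled
#'   (samples x cell types; each column has mean zero over the fitting
#'   samples).
#' @export
enrichmentScores <- function(scores) {
  stopifnot(is(scores, "CellScores"))
  if (!length(scores@totalTILs))
    stop("Total TILs not computed; run totalTILs() first")
  t <- scores@totalTILs
  if (length(t) < 3L) stop("at least 3 samples are required")
  if (stats::var(t) == 0) stop("Total TILs score has zero variance")
  enr <- apply(scores@scores, 2L,
               function(y) stats::resid(stats::lm(y ~ t)))
  dimnames(enr) <- dimnames(scores@scores)
  scores@enrichment <- enr
  scores
}

#' Calibrate a cell score to an absolute cell count
#'
#' Converts a log2-scale cell score to an absolute count using a
#' reference sample with a known count: the inferred count is
#' `referenceCount * 2^(score - referenceScore)`.  A reference with 500
#' macrophages and score 4 implies that a sample scoring 5 has 1000.
#'
#' @param score Cell score(s) of the query sample(s) (log2 units).
#' @param referenceScore Score of the reference sample for the same cell
#'   type.
#' @param referenceCount Known absolute cell count of the reference
#'   sample (> 0).
#' @return Inferred absolute count(s).
#' @examples
#' calibrateAbsolute(5, referenceScore = 4, referenceCount = 500)  # 1000
#' @export
calibrateAbsolute <- function(score, referenceScore, referenceCount) {
  .checkScalar(referenceScore, "referenceScore")
  .checkScalar(referenceCount, "referenceCount")
  if (referenceCount <= 0) stop("'referenceCount' must be positive")
  referenceCount * 2^(score - referenceScore)
}

#' Convert a log2 score difference to a fold change
#'
#' @param delta Difference in log2-scale scores.
#' @return `2^delta`, the implied fold change in abundance.
#' @examples
#' foldChange(2.58)   # ~5.97-fold
#' @export
foldChange <- function(delta) 2^delta

#' Report cell scores relative to a baseline group
#'
#' Subtracts from each cell score its mean over a set of baseline samples
#' (e.g. therapy-naive patients), so scores read as log2 fold changes
#' from the baseline average and the baseline group averages to zero for
#' every cell type.
#'
#' @param scores A [CellScores-class].
#' @param baselineIds Sample identifiers of the baseline group (must be a
#'   non-empty subset of the score rows).
#' @return A new [CellScores-class] with `scoreType =
#'   "baseline_relative"`.  Total TILs, if present, is shifted the same
#'   way; enrichment scores are dropped (they are defined on the raw
#'   scale).
#' @export
relativeToBaseline <- function(scores, baselineIds) {
  stopifnot(is(scores, "CellScores"))
  if (!length(baselineIds)) stop("baseline sample set is empty")
  missing <- setdiff(baselineIds, rownames(scores@scores))
  if (length(missing))
    stop("baseline samples not found: ", paste(missing, collapse = ", "))
  base <- colMeans(scores@scores[baselineIds, , drop = FALSE])
  scores@scores <- sweep(scores@scores, 2L, base)
  if (length(scores@totalTILs))
    scores@totalTILs <- scores@totalTILs -
      mean(scores@totalTILs[baselineIds])
  scores@enrichment <- matrix(numeric(), 0, 0)
  scores@scoreType <- "baseline_relative"
  scores
}

#' Normalize cell scores to an anchor cell type
#'
#' Subtracts one cell type's score from every score, per sample.  The
#' resulting values are log2 ratios to the anchor population and are
#' independent of any per-sample additive normalization factor — the
#' appropriate reading when reference-gene normalization is itself
#' confounded by sample composition (e.g. PBMCs).
#'
#' @param scores A [CellScores-class].
#' @param anchor Name of the anchor cell type (must be scored in every
#'   sample); e.g. `"T-cells"`.
#' @return A new [CellScores-class] with `scoreType =
#'   "anchored:<anchor>"`; the anchor column is identically zero.  Total
#'   TILs and enrichment are dropped.
#' @export
normalizeToCellType <- function(scores, anchor) {
  stopifnot(is(scores, "CellScores"))
  if (!anchor %in% colnames(scores@scores))
    stop("anchor cell type '", anchor, "' is not scored")
  scores@scores <- scores@scores - scores@scores[, anchor]
  scores@totalTILs <- numeric()
  scores@tilsInfo <- list()
  scores@enrichment <- matrix(numeric(), 0, 0)
  scores@scoreType <- paste0("anchored:", anchor)
  scores
}
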