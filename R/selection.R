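#' Select marker genes for one cell type from a similarity matrix
#'
#' Reconstructs the marker-selection procedure as a deterministic rule.
#' Candidates are clustered by average linkage on `1 - similarity`; every
#' cluster appearing at any dendrogram cut is scored by its mean
#' off-diagonal similarity, and the selected set starts from the largest
#' cluster whose mean exceeds `highThreshold` (falling back to
#' `moderateThreshold` when no cluster reaches the high bar, and to the
#' empty set when none reaches either).  Two refinements then emulate the
#' manual curation a heatmap invites:
#'
#' * **Slope-outlier pruning.** A gene pair that is strongly Pearson
#'   correlated (`|r| > highThreshold`) but whose similarity falls below
#'   `slopeRatio * |r|` betrays a non-unit slope (the similarity-to-
#'   correlation ratio is `2 s_x s_y / (s_x^2 + s_y^2)`, which is 1 only
#'   at equal variances).  The gene involved in the most such pairs is
#'   removed, iteratively, so a gene tracking the cluster at slope 2
#'   cannot ride in on its high correlation.
#' * **Core-coherence pruning.** A gene whose mean similarity to the rest
#'   of the cluster is below `coreRatio` times the mean similarity among
#'   the remaining genes is peeled off.  This is what identifies the
#'   "obvious subset": a tight core at 0.95 sheds a hanger-on at 0.6.
#'
#' Ties are broken lexicographically so selection is fully deterministic.
#'
#' @param avg A [SimilarityResult-class], typically from
#'   [averageSimilarity()].
#' @param candidates Candidate gene symbols; default all genes covered by
#'   `avg` (plus its recorded absent genes).
#' @param highThreshold Mean-similarity bar for confident clusters
#'   (default 0.6).
#' @param moderateThreshold Fallback bar (default 0.4); also the level at
#'   or below which a selection is flagged `discarded_low_similarity`.
#' @param exclusions Genes removed post hoc on domain knowledge, whatever
#'   their co-expression (reason `domain_exclusion`).
#' @param slopeRatio Minimum allowed similarity / |correlation| ratio
#'   within the selected cluster (default 0.9, tolerating exact slopes in
#'   about \[0.63, 1.6\]).
#' @param coreRatio Minimum allowed ratio of a gene's mean similarity to
#'   the cluster core's own mean (default 0.75).
#' @param cellType Name recorded in the report.
#' @return A [MarkerSelection-class].  A single candidate is returned
#'   unvalidated (`single_gene_unvalidated`): its quality cannot be
#'   assessed from co-expression alone.
#' @export
selectMarkers <- function(avg, candidates = NULL,
                          highThreshold = 0.6, moderateThreshold = 0.4,
                          exclusions = character(),
                          slopeRatio = 0.9, coreRatio = 0.75,
                          cellType = "cell type") {
  stopifnot(is(avg, "SimilarityResult"))
  exclusions <- canonicalSymbols(exclusions)
  if (is.null(candidates))
    candidates <- c(avg@genes, avg@absentGenes)
  candidates <- unique(canonicalSymbols(candidates))
  known <- c(avg@genes, avg@absentGenes, avg@droppedGenes)
  if (!any(candidates %in% known))
    stop("none of the candidates are covered by the similarity matrix")

  S <- avg@similarity
  present <- intersect(candidates, avg@genes)
  # genes with no usable pair (all-NA off-diagonal) behave as absent
  if (length(present) >= 2L) {
    off <- S[present, present, drop = FALSE]
    diag(off) <- NA
    usable <- rowSums(!is.na(off)) > 0
    present <- present[usable | length(present) == 1L]
  }
  absent <- setdiff(candidates, present)

  discard <- list()
  if (length(absent))
    discard$absent <- data.frame(gene = absent, reason = "absent_from_data",
                                 stringsAsFactors = FALSE)

  finish <- function(selected, extra = NULL, status = NULL) {
    dd <- do.call(rbind, c(discard, list(extra)))
    if (is.null(dd)) dd <- data.frame(gene = character(),
                                      reason = character())
    ms <- if (length(selected) >= 2L)
      .offDiagMean(S[selected, selected, drop = FALSE]) else NA_real_
    if (is.null(status))
      status <- if (length(selected) == 0L ||
                    (!is.na(ms) && ms <= moderateThreshold))
        "discarded_low_similarity" else "accepted"
    new("MarkerSelection", cellType = cellType, candidates = candidates,
        selected = selected, discarded = dd, meanSimilarity = ms,
        status = status, meanExpression = NA_real_)
  }

  if (length(candidates) == 1L && length(present) == 1L) {
    if (present %in% exclusions)
      return(finish(character(),
                    data.frame(gene = present, reason = "domain_exclusion"),
                    status = "discarded_low_similarity"))
    return(finish(present, status = "single_gene_unvalidated"))
  }
  if (length(present) == 0L)
    return(finish(character()))
  if (length(present) == 1L) {
    # lone survivor of a larger candidate list: nothing to cluster
    return(finish(character(),
                  data.frame(gene = present, reason = "low_similarity")))
  }

  Sp <- S[present, present]
  Rp <- avg@correlation[present, present]
  Sp0 <- Sp; Sp0[is.na(Sp0)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - Sp0), method = "average")

  # every cluster induced at any dendrogram cut, size >= 2
  clusters <- list()
  for (k in seq_len(length(present))) {
    ct <- stats::cutree(hc, k = k)
    for (cl in split(names(ct), ct))
      if (length(cl) >= 2L) clusters[[paste(sort(cl), collapse = "|")]] <-
          sort(cl)
  }
  cmean <- vapply(clusters, function(cl)
    .offDiagMean(Sp[cl, cl, drop = FALSE]), numeric(1))

  pick <- function(th) {
    q <- which(cmean > th)
    if (!length(q)) return(NULL)
    sz <- lengths(clusters[q])
    ord <- order(-sz, -cmean[q], names(clusters)[q])
    clusters[[q[ord[1L]]]]
  }
  sel <- pick(highThreshold)
  if (is.null(sel)) sel <- pick(moderateThreshold)
  if (is.null(sel)) sel <- character()

  pruned <- list()
  geneMeanSim <- function(g, set)
    mean(Sp[g, setdiff(set, g)], na.rm = TRUE)

  # slope-outlier pruning
  repeat {
    if (length(sel) < 3L) break
    flags <- integer(length(sel)); names(flags) <- sel
    for (i in seq_along(sel)) for (j in seq_along(sel)) {
      if (i >= j) next
      r <- abs(Rp[sel[i], sel[j]]); s <- Sp[sel[i], sel[j]]
      if (!is.na(r) && !is.na(s) && r > highThreshold && s < slopeRatio * r)
        flags[c(i, j)] <- flags[c(i, j)] + 1L
    }
    if (!any(flags > 0L)) break
    ms <- vapply(sel, geneMeanSim, numeric(1), set = sel)
    victim <- sel[order(-flags, ms, sel)][1L]
    pruned[[victim]] <- "non_unit_slope_cluster"
    sel <- setdiff(sel, victim)
  }

  # core-coherence pruning
  repeat {
    if (length(sel) < 3L) break
    ms <- vapply(sel, geneMeanSim, numeric(1), set = sel)
    worst <- sel[order(ms, sel)][1L]
    core <- setdiff(sel, worst)
    coreMean <- .offDiagMean(Sp[core, core, drop = FALSE])
    if (is.na(coreMean) || ms[worst] >= coreRatio * coreMean) break
    pruned[[worst]] <- if (!is.na(mean(abs(Rp[worst, core]))) &&
                           mean(abs(Rp[worst, core])) > highThreshold &&
                           ms[worst] < slopeRatio *
                             mean(abs(Rp[worst, core])))
      "non_unit_slope_cluster" else "low_similarity"
    sel <- setdiff(sel, worst)
  }

  # domain-knowledge overrides, applied last
  domained <- intersect(sel, exclusions)
  sel <- setdiff(sel, domained)

  rest <- setdiff(present, c(sel, names(pruned), domained))
  rows <- list()
  if (length(rest)) {
    reason <- vapply(rest, function(g) {
      if (!length(sel)) return("low_similarity")
      r <- mean(abs(Rp[g, sel]), na.rm = TRUE)
      s <- mean(Sp[g, sel], na.rm = TRUE)
      if (!is.na(r) && r > highThreshold && s < slopeRatio * r)
        "non_unit_slope_cluster" else "low_similarity"
    }, character(1))
    rows$rest <- data.frame(gene = rest, reason = reason,
                            stringsAsFactors = FALSE)
  }
  if (length(pruned))
    rows$pruned <- data.frame(gene = names(pruned),
                              reason = unlist(pruned),
                              stringsAsFactors = FALSE)
  if (length(domained))
    rows$dom <- data.frame(gene = domained, reason = "domain_exclusion",
                           stringsAsFactors = FALSE)
  finish(sel, do.call(rbind, rows))
}

#' Final quality triage of cell-type marker selections
#'
#' Applies the panel-level discard rule: cell types whose selected markers
#' have mean pairwise similarity below `discardThreshold` are marked
#' `discarded_low_similarity`; single-gene cell types stay unvalidated but
#' retained.  When an expression matrix is supplied, the mean log2
#' expression of each cell type's selected genes is attached as a
#' diagnostic (low-expression marker sets tend to look worse simply
#' through measurement error).
#'
#' @param reports List of [MarkerSelection-class] objects.
#' @param discardThreshold Mean-similarity cutoff (default 0.4; strictly
#'   below discards, so a 0.40 cell type survives).
#' @param expr Optional log2 [TILExpression-class] for the mean-expression
#'   diagnostic.
#' @return The list of reports with final statuses (and diagnostics).
#' @export
cellTypeQuality <- function(reports, discardThreshold = 0.4, expr = NULL) {
  stopifnot(all(vapply(reports, is, logical(1), "MarkerSelection")))
  lapply(reports, function(rep) {
    if (rep@status != "single_gene_unvalidated" &&
        !is.na(rep@meanSimilarity) &&
        rep@meanSimilarity < discardThreshold)
      rep@status <- "discarded_low_similarity"
    if (!is.null(expr) && length(rep@selected)) {
      g <- intersect(rep@selected, geneIds(expr))
      if (length(g))
        rep@meanExpression <-
          mean(exprValues(expr)[g, , drop = FALSE])
    }
    rep
  })
}
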