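# build a SimilarityResult directly from a similarity matrix (correlation
# defaults to the same values, i.e. equal-variance genes)
mkSimRes <- function(s, rho = s, absent = character()) {
  g <- rownames(s)
  new("SimilarityResult", genes = g, similarity = s, correlation = rho,
      nSamples = 100L, datasetLabel = "test", absentGenes = absent,
      droppedGenes = character(),
      pairCounts = matrix(1L, nrow(s), ncol(s), dimnames = dimnames(s)))
}

symMat <- function(genes, fill) {
  s <- matrix(fill, length(genes), length(genes),
              dimnames = list(genes, genes))
  diag(s) <- 1
  s
}

test_that("mutually perfect candidates are all selected", {
  s <- symMat(c("A", "B", "C", "D"), 1)
  rep <- selectMarkers(mkSimRes(s), cellType = "perfect")
  expect_setequal(selectedMarkers(rep), c("A", "B", "C", "D"))
  expect_equal(rep@meanSimilarity, 1)
  expect_identical(rep@status, "accepted")
})

test_that("a single candidate is retained but flagged unvalidated", {
  v <- rbind(ONLY = c(1, 2, 3, 4), OTHER = c(4, 3, 2, 1))
  colnames(v) <- paste0("s", 1:4)
  res <- similarityMatrix(mkExpr(v))
  rep <- selectMarkers(res, candidates = "ONLY", cellType = "Th1-like")
  expect_identical(selectedMarkers(rep), "ONLY")
  expect_identical(rep@status, "single_gene_unvalidated")
  expect_true(is.na(rep@meanSimilarity))
})

test_that("candidates absent from the data are reported, not fabricated", {
  s <- symMat(c("A", "B"), 0.9)
  rep <- selectMarkers(mkSimRes(s, absent = "GHOST"),
                       candidates = c("A", "B", "GHOST"))
  expect_setequal(selectedMarkers(rep), c("A", "B"))
  tab <- selectionTable(rep)
  expect_identical(tab$reason[tab$gene == "GHOST"], "absent_from_data")
})

test_that("domain exclusions override co-expression, with their own reason", {
  s <- symMat(c("CD8A", "CD8B", "FLT3LG", "GZMM"), 0.85)
  rep <- selectMarkers(mkSimRes(s), exclusions = c("FLT3LG", "GZMM"),
                       cellType = "CD8 T cells")
  expect_setequal(selectedMarkers(rep), c("CD8A", "CD8B"))
  tab <- selectionTable(rep)
  expect_setequal(tab$gene[tab$reason %in% "domain_exclusion"],
                  c("FLT3LG", "GZMM"))
})

test_that("the archetype scenario always selects the two unit-slope markers", {
  for (seed in c(1, 17, 99)) {
    sim <- simulateArchetypes(seed = seed)
    res <- similarityMatrix(simExpression(sim))
    rep <- selectMarkers(res, cellType = "target")
    expect_setequal(selectedMarkers(rep), c("GENE1", "GENE2"))
    tab <- selectionTable(rep)
    expect_identical(tab$reason[tab$gene == "GENE3"], "low_similarity")
    expect_identical(tab$reason[tab$gene == "GENE4"],
                     "non_unit_slope_cluster")
    # the slope-2 gene is highly correlated yet below-par in similarity
    expect_gt(correlationValues(res)["GENE1", "GENE4"], 0.95)
    expect_gt(similarityValues(res)["GENE1", "GENE4"], 0.6)
    expect_lt(similarityValues(res)["GENE1", "GENE4"], 0.95)
  }
})

test_that("selection falls back to the moderate threshold", {
  s <- symMat(c("A", "B", "C"), 0.5)   # qualifies at 0.4, not 0.6
  rep <- selectMarkers(mkSimRes(s))
  expect_setequal(selectedMarkers(rep), c("A", "B", "C"))
  expect_identical(rep@status, "accepted")

  s2 <- symMat(c("A", "B", "C"), 0.2)  # nothing qualifies
  rep2 <- selectMarkers(mkSimRes(s2))
  expect_length(selectedMarkers(rep2), 0)
  expect_identical(rep2@status, "discarded_low_similarity")
})

test_that("selection is deterministic and partitions the candidates", {
  set.seed(23)
  sim <- simulateArchetypes(seed = 23)
  res <- similarityMatrix(simExpression(sim))
  r1 <- selectMarkers(res); r2 <- selectMarkers(res)
  expect_identical(selectedMarkers(r1), selectedMarkers(r2))
  expect_setequal(c(selectedMarkers(r1), r1@discarded$gene),
                  r1@candidates)
})

test_that("cellTypeQuality discards below 0.4 and spares single genes", {
  good <- selectMarkers(mkSimRes(symMat(c("A", "B"), 0.81)),
                        cellType = "good")
  weak <- selectMarkers(mkSimRes(symMat(c("C", "D"), 0.45)),
                        cellType = "weak")
  out <- cellTypeQuality(list(good, weak), discardThreshold = 0.4)
  expect_identical(out[[1]]@status, "accepted")
  expect_identical(out[[2]]@status, "accepted")

  # force a sub-threshold mean: 0.39 must be discarded
  weak@meanSimilarity <- 0.39
  out2 <- cellTypeQuality(list(weak))[[1]]
  expect_identical(out2@status, "discarded_low_similarity")

  # exactly 0.40 survives (strictly-below rule)
  weak@meanSimilarity <- 0.40
  expect_identical(cellTypeQuality(list(weak))[[1]]@status, "accepted")

  single <- new("MarkerSelection", cellType = "Treg",
                candidates = "FOXP3", selected = "FOXP3",
                discarded = data.frame(gene = character(),
                                       reason = character()),
                meanSimilarity = NA_real_,
                status = "single_gene_unvalidated",
                meanExpression = NA_real_)
  expect_identical(cellTypeQuality(list(single))[[1]]@status,
                   "single_gene_unvalidated")
})

test_that("cellTypeQuality attaches the mean-expression diagnostic", {
  v <- rbind(A = c(4, 6, 5, 7), B = c(5, 7, 6, 8))
  colnames(v) <- paste0("s", 1:4)
  rep <- selectMarkers(similarityMatrix(mkExpr(v)), cellType = "x")
  out <- cellTypeQuality(list(rep), expr = mkExpr(v))[[1]]
  expect_equal(out@meanExpression, mean(v))
})
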