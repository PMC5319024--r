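test_that("cell scores are the mean log2 expression of available markers", {
  v <- rbind(CD8A = c(4, 2), CD8B = c(6, 4), CD3D = c(5, 5),
             CD3E = c(7, 3))
  colnames(v) <- c("s1", "s2")
  ms <- MarkerSet(list("CD8 T cells" = c("CD8A", "CD8B"),
                       "T-cells" = c("CD3D", "CD3E")))
  sc <- cellScores(mkExpr(v), ms)
  expect_equal(scoreMatrix(sc)["s1", "CD8 T cells"], 5)
  expect_equal(scoreMatrix(sc)["s2", "T-cells"], 4)
  expect_identical(scoreProvenance(sc)[["CD8 T cells"]],
                   c("CD8A", "CD8B"))
})

test_that("the derived CD4 score is the T-cell score minus the CD8 score", {
  v <- rbind(CD3D = c(7, 6), CD8A = c(5, 2))
  colnames(v) <- c("s1", "s2")
  ms <- MarkerSet(list("T-cells" = "CD3D", "CD8 T cells" = "CD8A"),
                  derived = list("CD4 cells" = list(
                    from = "T-cells", minus = "CD8 T cells")))
  sc <- cellScores(mkExpr(v), ms)
  expect_equal(unname(scoreMatrix(sc)[, "CD4 cells"]), c(2, 4))
  # CD4 is skipped (with a warning) when a parent score is missing
  ms2 <- MarkerSet(list("T-cells" = "CD3D", "CD8 T cells" = "CD8B"),
                   derived = derivedScores(ms))
  expect_warning(
    expect_warning(sc2 <- cellScores(mkExpr(v), ms2), "no marker genes"),
    "CD4 cells")
  expect_false("CD4 cells" %in% colnames(scoreMatrix(sc2)))
})

test_that("missing markers are averaged over the available subset", {
  v <- rbind(CD8A = c(4, 2), CD3D = c(6, 8))
  colnames(v) <- c("s1", "s2")
  ms <- MarkerSet(list(ct = c("CD8A", "CD3D", "GONE1", "GONE2")))
  sc <- cellScores(mkExpr(v), ms)
  expect_equal(unname(scoreMatrix(sc)[, "ct"]), c(5, 5))
  expect_setequal(scoreProvenance(sc)$ct, c("CD8A", "CD3D"))
  expect_error(cellScores(mkExpr(v), ms, allowMissing = FALSE), "GONE1")
  ms3 <- MarkerSet(list(ct = "CD8A", empty = "GONE1"))
  expect_warning(sc3 <- cellScores(mkExpr(v), ms3), "empty")
  expect_identical(colnames(scoreMatrix(sc3)), "ct")
})

test_that("scoring ignores marker order and duplicate listings", {
  v <- rbind(A = c(1, 2, 3), B = c(4, 5, 9))
  colnames(v) <- paste0("s", 1:3)
  s1 <- cellScores(mkExpr(v), MarkerSet(list(ct = c("A", "B"))))
  s2 <- cellScores(mkExpr(v), MarkerSet(list(ct = c("B", "A"))))
  expect_equal(scoreMatrix(s1), scoreMatrix(s2))
})

test_that("scoring requires log2 input", {
  v <- rbind(A = c(1, 2), B = c(3, 4)); colnames(v) <- c("s1", "s2")
  expect_error(cellScores(mkExpr(v, scale = "raw_counts"),
                          MarkerSet(list(ct = c("A", "B")))), "log2")
})

test_that("Total TILs includes exactly the scores correlated with CD45", {
  set.seed(31)
  n <- 500
  cd45 <- rnorm(n, 8, 1)
  # designed correlations: affine (1), strong, moderate, none
  mkScore <- function(noiseSD) cd45 + rnorm(n, 0, noiseSD)
  scores <- cbind(affine = 2 * cd45 + 1,
                  strong = mkScore(0.48),   # r ~ 0.9
                  weak   = mkScore(3.2),    # r ~ 0.3
                  indep  = rnorm(n, 5, 1))
  rownames(scores) <- paste0("s", seq_len(n))
  cs <- new("CellScores", scores = scores, totalTILs = numeric(),
            tilsInfo = list(), enrichment = matrix(numeric(), 0, 0),
            provenance = list(), scoreType = "log2")
  out <- totalTILs(cs, cd45 = cd45)
  inc <- tilsInclusion(out)
  expect_true(all(c("affine", "strong") %in% inc$included))
  expect_true(all(c("weak", "indep") %in% inc$excluded))
  expect_equal(tilsScore(out),
               rowMeans(scores[, inc$included, drop = FALSE]))
  # frozen inclusion list bypasses the correlation rule
  frozen <- totalTILs(cs, cd45 = cd45, include = c("affine", "indep"))
  expect_setequal(tilsInclusion(frozen)$included, c("affine", "indep"))
})

test_that("Total TILs defaults to the CD45 column and guards its inputs", {
  scores <- cbind(CD45 = c(1, 2, 3, 4), tcell = c(1.1, 2.2, 2.9, 4.1))
  rownames(scores) <- paste0("s", 1:4)
  cs <- new("CellScores", scores = scores, totalTILs = numeric(),
            tilsInfo = list(), enrichment = matrix(numeric(), 0, 0),
            provenance = list(), scoreType = "log2")
  out <- totalTILs(cs)
  expect_setequal(tilsInclusion(out)$included, c("CD45", "tcell"))

  indep <- cbind(a = c(1, 5, 2, 4), b = c(2, 2.1, 1.9, 2))
  rownames(indep) <- paste0("s", 1:4)
  cs2 <- new("CellScores", scores = indep, totalTILs = numeric(),
             tilsInfo = list(), enrichment = matrix(numeric(), 0, 0),
             provenance = list(), scoreType = "log2")
  expect_error(totalTILs(cs2, cd45 = c(4, 0.5, 3, 1)), "threshold")
  expect_error(totalTILs(cs2, cd45 = 1:3), "align")
})

test_that("enrichment scores are OLS residuals with the stated geometry", {
  tils <- c(1, 1, -1, -1)                      # mean-centered
  offsets <- c(1, -1, 0, 0)                    # orthogonal to tils
  scores <- cbind(same = tils, offset = tils + offsets)
  rownames(scores) <- paste0("s", 1:4)
  cs <- new("CellScores", scores = scores, totalTILs = tils,
            tilsInfo = list(), enrichment = matrix(numeric(), 0, 0),
            provenance = list(), scoreType = "log2")
  out <- enrichmentScores(cs)
  enr <- enrichmentMatrix(out)
  expect_equal(unname(enr[, "same"]), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(enr[, "offset"]), offsets, tolerance = 1e-12)
  expect_equal(unname(colSums(enr)), c(0, 0), tolerance = 1e-12)

  csz <- cs; csz@totalTILs <- rep(1, 4)
  expect_error(enrichmentScores(csz), "zero variance")
})

test_that("absolute calibration doubles counts per score unit", {
  expect_equal(calibrateAbsolute(5, 4, 500), 1000)
  expect_equal(calibrateAbsolute(4, 4, 500), 500)
  expect_lte(abs(calibrateAbsolute(2.58, 0, 100) - 597), 1)
  expect_error(calibrateAbsolute(5, 4, -1), "positive")
  # calibrating then re-deriving the log2 difference is exact
  sc <- 6.37; ref <- 4.21
  expect_equal(log2(calibrateAbsolute(sc, ref, 250) / 250), sc - ref,
               tolerance = 1e-12)
})

test_that("baseline-relative scores zero the baseline group", {
  scores <- cbind(ct1 = c(3, 5, 7), ct2 = c(2, 4, 9))
  rownames(scores) <- c("b1", "b2", "q")
  cs <- new("CellScores", scores = scores, totalTILs = numeric(),
            tilsInfo = list(), enrichment = matrix(numeric(), 0, 0),
            provenance = list(), scoreType = "log2")
  out <- relativeToBaseline(cs, c("b1", "b2"))
  expect_equal(unname(scoreMatrix(out)["q", "ct1"]), 3)  # 7 - mean(3,5)
  expect_equal(unname(colMeans(scoreMatrix(out)[c("b1", "b2"), ])),
               c(0, 0))
  expect_identical(out@scoreType, "baseline_relative")

  one <- relativeToBaseline(cs, "q")
  expect_equal(unname(scoreMatrix(one)["q", ]), c(0, 0))
  all3 <- relativeToBaseline(cs, rownames(scores))
  expect_equal(unname(colMeans(scoreMatrix(all3))), c(0, 0))
  expect_error(relativeToBaseline(cs, character()), "empty")
  expect_error(relativeToBaseline(cs, "nope"), "nope")
})

test_that("anchor normalization yields per-sample contrasts", {
  v <- rbind(CD3D = c(8, 6), MS4A1 = c(6, 7))
  colnames(v) <- c("s1", "s2")
  ms <- MarkerSet(list("T-cells" = "CD3D", "B-cells" = "MS4A1"))
  sc <- cellScores(mkExpr(v), ms)
  out <- normalizeToCellType(sc, "T-cells")
  expect_equal(unname(scoreMatrix(out)[, "T-cells"]), c(0, 0))
  expect_equal(unname(scoreMatrix(out)["s1", "B-cells"]), -2)
  expect_identical(out@scoreType, "anchored:T-cells")
  expect_error(normalizeToCellType(sc, "NK cells"), "NK cells")

  # contrasts are invariant to per-sample additive normalization shifts
  shifts <- c(1.3, -0.8)
  sc2 <- cellScores(mkExpr(sweep(v, 2, shifts, `+`)), ms)
  expect_equal(scoreMatrix(normalizeToCellType(sc2, "T-cells")),
               scoreMatrix(out))
})

test_that("adding c to a sample's genes shifts its scores and TILs by c", {
  set.seed(41)
  v <- matrix(rnorm(40, 7, 1), 4,
              dimnames = list(c("A1", "A2", "B1", "B2"),
                              paste0("s", 1:10)))
  ms <- MarkerSet(list(ctA = c("A1", "A2"), ctB = c("B1", "B2")))
  sc <- cellScores(mkExpr(v), ms)
  sc <- totalTILs(sc, cd45 = colMeans(v), include = c("ctA", "ctB"))

  c0 <- 1.7
  v2 <- v; v2[, "s3"] <- v2[, "s3"] + c0
  sc2 <- cellScores(mkExpr(v2), ms)
  sc2 <- totalTILs(sc2, cd45 = colMeans(v2), include = c("ctA", "ctB"))
  expect_equal(scoreMatrix(sc2)["s3", ],
               scoreMatrix(sc)["s3", ] + c0, tolerance = 1e-12)
  expect_equal(scoreMatrix(sc2)[-3, ], scoreMatrix(sc)[-3, ],
               tolerance = 1e-12)
  expect_equal(tilsScore(sc2)["s3"], tilsScore(sc)["s3"] + c0,
               tolerance = 1e-12)
})
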