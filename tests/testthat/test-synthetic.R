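# two-cell-type config with a shared contaminant, used in several tests
contaminantConfig <- function(seed, loading = 0) {
  simConfig(
    nSamples = 500,
    cellTypes = data.frame(name = c("cellA", "cellB"),
                           log2_mean = c(6, 6), log2_sd = c(1, 1)),
    genes = data.frame(
      symbol = c(paste0("MA", 1:4), "CONT", "JUNK"),
      role = c(rep("pure", 4), "contaminant", "noise"),
      cell_type = c(rep("cellA", 4), "cellA;cellB", ""),
      constant = c(4, 2, 8, 4, 4, 32),
      noise_sd = c(rep(0.1, 5), 1),
      gamma = NA,
      stringsAsFactors = FALSE),
    infiltrateLoading = loading, seed = seed)
}

test_that("simulation is deterministic given the seed", {
  s1 <- simulateDataset(contaminantConfig(9))
  s2 <- simulateDataset(contaminantConfig(9))
  expect_identical(exprValues(simExpression(s1)),
                   exprValues(simExpression(s2)))
  expect_identical(trueAbundance(s1), trueAbundance(s2))
  s3 <- simulateDataset(contaminantConfig(10))
  expect_false(identical(exprValues(simExpression(s1)),
                         exprValues(simExpression(s3))))
})

test_that("noiseless pure markers are perfectly similar by construction", {
  cfg <- simConfig(
    nSamples = 50,
    cellTypes = data.frame(name = "ct", log2_mean = 5, log2_sd = 1),
    genes = data.frame(symbol = c("M1", "M2"), role = "pure",
                       cell_type = "ct", constant = c(2, 8),
                       noise_sd = 0, gamma = NA),
    infiltrateLoading = 0, seed = 2)
  sim <- simulateDataset(cfg)
  v <- exprValues(simExpression(sim))
  expect_equal(pairwiseSimilarity(v["M1", ], v["M2", ]), 1,
               tolerance = 1e-12)
})

test_that("a noiseless slope gene hits the closed form 2b/(1+b^2)", {
  cfg <- simConfig(
    nSamples = 100,
    cellTypes = data.frame(name = "ct", log2_mean = 5, log2_sd = 1),
    genes = data.frame(symbol = c("M1", "S2"),
                       role = c("pure", "slope"), cell_type = "ct",
                       constant = c(4, 1), noise_sd = 0,
                       gamma = c(NA, 2)),
    infiltrateLoading = 0, seed = 3)
  v <- exprValues(simExpression(simulateDataset(cfg)))
  # empirical abundance variance cancels exactly: 2*2/(1+4)
  expect_equal(pairwiseSimilarity(v["M1", ], v["S2", ]), 0.8,
               tolerance = 1e-12)
})

test_that("pure markers regress on true abundance with slope 1", {
  sim <- simulateDataset(contaminantConfig(12))
  v <- exprValues(simExpression(sim))
  ab <- trueAbundance(sim)[, "cellA"]
  for (g in paste0("MA", 1:4)) {
    slope <- unname(coef(lm(v[g, ] ~ ab))[2])
    expect_equal(slope, 1, tolerance = 0.05)
  }
})

test_that("cell scores track true abundances almost perfectly at low noise", {
  sim <- simulateDataset(contaminantConfig(13))
  sc <- cellScores(simExpression(sim),
                   MarkerSet(list(cellA = paste0("MA", 1:4))))
  expect_gt(cor(scoreMatrix(sc)[, "cellA"],
                trueAbundance(sim)[, "cellA"]), 0.99)
})

test_that("marker similarity decreases monotonically with gene noise", {
  sds <- c(0, 0.2, 0.5, 1.0)
  meanSim <- sapply(sds, function(sd) {
    mean(sapply(1:50, function(seed) {
      cfg <- simConfig(
        nSamples = 200,
        cellTypes = data.frame(name = "ct", log2_mean = 5, log2_sd = 1),
        genes = data.frame(symbol = c("M1", "M2"), role = "pure",
                           cell_type = "ct", constant = c(2, 4),
                           noise_sd = sd, gamma = NA),
        infiltrateLoading = 0, seed = 1000 + seed)
      v <- exprValues(simExpression(simulateDataset(cfg)))
      pairwiseSimilarity(v["M1", ], v["M2", ])
    }))
  })
  expect_true(all(diff(meanSim) < 0))
  expect_gt(meanSim[1], 0.999)
})

test_that("true markers are recovered exactly in the contaminant scenario", {
  sim <- simulateDataset(contaminantConfig(11))
  res <- similarityMatrix(simExpression(sim))
  s <- similarityValues(res)
  markers <- paste0("MA", 1:4)
  expect_gt(mean(s[markers, markers][upper.tri(s[markers, markers])]),
            0.9)
  # a gene fed equally by two independent cell types lands well below the
  # pure-marker band (its log2 variance is roughly halved by the mixing)
  contSim <- s["CONT", markers]
  expect_true(all(contSim > 0.5 & contSim < 0.75))
  rep <- selectMarkers(res, cellType = "cellA")
  expect_setequal(selectedMarkers(rep), markers)
  expect_true(all(c("CONT", "JUNK") %in% rep@discarded$gene))
})

test_that("the shared infiltrate factor induces the designed correlation", {
  cfg <- simConfig(
    nSamples = 4000,
    cellTypes = data.frame(name = c("a", "b"), log2_mean = 5,
                           log2_sd = 1),
    genes = data.frame(symbol = c("GA", "GB"), role = "pure",
                       cell_type = c("a", "b"), constant = 4,
                       noise_sd = 0, gamma = NA),
    infiltrateLoading = 0.7, seed = 21)
  ab <- trueAbundance(simulateDataset(cfg))
  expect_equal(cor(ab[, "a"], ab[, "b"]), 0.49, tolerance = 0.05)
})

test_that("simConfig reports all invalid fields at once", {
  ct <- data.frame(name = "ct", log2_mean = 5, log2_sd = 1)
  g <- data.frame(symbol = "M1", role = "pure", cell_type = "ct",
                  constant = 4, noise_sd = 0.1, gamma = NA)
  expect_error(simConfig(1, ct, g, seed = 1), "nSamples")
  gbad <- g; gbad$role <- "mystery"; gbad$constant <- -2
  err <- tryCatch(simConfig(10, ct, gbad, seed = 1),
                  error = conditionMessage)
  expect_match(err, "role")
  expect_match(err, "constant")
  expect_error(simConfig(10, ct, g, infiltrateLoading = 2, seed = 1),
               "infiltrateLoading")
  expect_error(simConfig(10, ct, g), "seed")
  gslope <- g; gslope$role <- "slope"
  expect_error(simConfig(10, ct, gslope, seed = 1), "gamma")
})

test_that("the archetype scenario has the documented geometry", {
  sim <- simulateArchetypes(seed = 4)
  roles <- geneRoles(sim)
  expect_identical(roles$role,
                   c("pure", "pure", "noise", "slope"))
  expect_equal(roles$gamma[4], 2)
  s <- similarityValues(similarityMatrix(simExpression(sim)))
  expect_gt(s["GENE1", "GENE2"], 0.95)
  expect_lt(max(abs(s["GENE3", c("GENE1", "GENE2", "GENE4")])), 0.2)
  expect_gt(s["GENE1", "GENE4"], 0.6)
  expect_lt(s["GENE1", "GENE4"], 0.95)
})
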