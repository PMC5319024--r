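#' Build a simulation configuration
#'
#' Describes a synthetic bulk-expression experiment driven by latent
#' cell-type abundances.  Abundances are drawn on the log2 scale; each
#' cell type's abundance loads on a shared "total infiltrate" factor
#' (mimicking the strong mutual correlation of immune populations in real
#' tumors) with the remainder independent.  Genes come in four archetypes:
#'
#' * `pure` — expressed at a fixed linear-scale constant per cell of one
#'   cell type: log2 expression = log2(constant) + abundance + noise.
#' * `contaminant` — expressed equally by two or more cell types; the
#'   linear-scale contributions are summed before logging, matching the
#'   physical mixing of cells in bulk tissue.
#' * `slope` — tracks one cell type's abundance with slope `gamma != 1`
#'   (co-regulated but not abundance-stable; the archetype the similarity
#'   statistic exists to reject).
#' * `noise` — independent of all abundances: log2(constant) plus
#'   Gaussian noise.
#'
#' @param nSamples Number of samples.
#' @param cellTypes `data.frame(name, log2_mean, log2_sd)`.
#' @param genes `data.frame(symbol, role, cell_type, constant, noise_sd,
#'   gamma)`; `cell_type` may join several names with `";"` for
#'   contaminants; `gamma` is required for `slope` genes and ignored
#'   otherwise.
#' @param infiltrateLoading Loading of the shared infiltrate factor on
#'   every cell type (default 0.7); 0 makes cell types independent.
#' @param seed Mandatory RNG seed.
#' @return A validated [SimulationConfig-class]; invalid fields are
#'   reported together in one error.
#' @seealso [simulateDataset()], [simulateArchetypes()]
#' @export
simConfig <- function(nSamples, cellTypes, genes,
                      infiltrateLoading = 0.7, seed) {
  errs <- character()
  if (missing(seed) || is.null(seed) || is.na(seed))
    errs <- c(errs, "seed is mandatory")
  if (!is.numeric(nSamples) || nSamples < 2)
    errs <- c(errs, "nSamples must be >= 2")
  need <- c("name", "log2_mean", "log2_sd")
  if (!is.data.frame(cellTypes) || !all(need %in% names(cellTypes)))
    errs <- c(errs, paste("cellTypes needs columns:",
                          paste(need, collapse = ", ")))
  else if (any(cellTypes$log2_sd < 0))
    errs <- c(errs, "cellTypes$log2_sd must be non-negative")
  gneed <- c("symbol", "role", "cell_type", "constant", "noise_sd")
  if (!is.data.frame(genes) || !all(gneed %in% names(genes)))
    errs <- c(errs, paste("genes needs columns:",
                          paste(gneed, collapse = ", ")))
  else {
    if (!"gamma" %in% names(genes)) genes$gamma <- NA_real_
    if (!all(genes$role %in% c("pure", "contaminant", "slope", "noise")))
      errs <- c(errs, "gene role must be pure/contaminant/slope/noise")
    if (any(genes$noise_sd < 0))
      errs <- c(errs, "genes$noise_sd must be non-negative")
    if (any(genes$constant <= 0))
      errs <- c(errs, "genes$constant must be positive")
    if (any(genes$role == "slope" & is.na(genes$gamma)))
      errs <- c(errs, "slope genes require gamma")
    if (is.data.frame(cellTypes) && all(need %in% names(cellTypes))) {
      used <- unlist(strsplit(genes$cell_type[genes$role != "noise"], ";"))
      unknown <- setdiff(used, cellTypes$name)
      if (length(unknown))
        errs <- c(errs, paste("genes reference unknown cell type(s):",
                              paste(unique(unknown), collapse = ", ")))
      simulated <- cellTypes$name
      covered <- unique(unlist(strsplit(
        genes$cell_type[genes$role != "noise"], ";")))
      if (!all(simulated %in% covered) && !length(errs))
        errs <- c(errs, paste("every simulated cell type needs at least",
                              "one gene"))
    }
    if (anyDuplicated(genes$symbol))
      errs <- c(errs, "duplicate gene symbols in config")
  }
  if (!is.numeric(infiltrateLoading) || abs(infiltrateLoading) > 1)
    errs <- c(errs, "infiltrateLoading must lie in [-1, 1]")
  if (length(errs))
    stop("invalid simulation config:\n  - ",
         paste(errs, collapse = "\n  - "))
  new("SimulationConfig", nSamples = as.integer(nSamples),
      cellTypes = cellTypes, genes = genes,
      infiltrateLoading = infiltrateLoading, seed = as.integer(seed))
}

#' Simulate a bulk expression dataset with known ground truth
#'
#' Draws latent log2 abundances per the config, generates each gene per
#' its archetype (see [simConfig()]), and returns the log2 expression
#' matrix together with the true abundances and the gene roles.  Output
#' is deterministic given the config seed.
#'
#' @param config A [SimulationConfig-class].
#' @return A [TILSimulation-class].
#' @export
simulateDataset <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed)
  n <- config@nSamples
  ct <- config@cellTypes
  lam <- config@infiltrateLoading
  z <- stats::rnorm(n)                      # shared infiltrate factor
  ab <- sapply(seq_len(nrow(ct)), function(i) {
    ct$log2_mean[i] + ct$log2_sd[i] *
      (lam * z + sqrt(1 - lam^2) * stats::rnorm(n))
  })
  ab <- matrix(ab, nrow = n,
               dimnames = list(sprintf("sample_%03d", seq_len(n)),
                               ct$name))
  g <- config@genes
  expr <- matrix(NA_real_, nrow(g), n,
                 dimnames = list(canonicalSymbols(g$symbol),
                                 rownames(ab)))
  for (i in seq_len(nrow(g))) {
    noise <- stats::rnorm(n, 0, g$noise_sd[i])
    types <- strsplit(g$cell_type[i], ";")[[1L]]
    expr[i, ] <- switch(g$role[i],
      pure = log2(g$constant[i]) + ab[, types[1L]] + noise,
      contaminant =
        log2(rowSums(g$constant[i] * 2^ab[, types, drop = FALSE])) + noise,
      slope = log2(g$constant[i]) + g$gamma[i] * ab[, types[1L]] + noise,
      noise = log2(g$constant[i]) + noise)
  }
  roles <- data.frame(gene = rownames(expr), role = g$role,
                      cell_type = g$cell_type, gamma = g$gamma,
                      stringsAsFactors = FALSE)
  new("TILSimulation",
      expression = TILExpression(expr, scale = "log2",
                                 metadata = list(seed = config@seed)),
      trueAbundance = ab, geneRoles = roles, config = config)
}

#' Canonical four-gene marker-QC demonstration scenario
#'
#' Simulates the standard walkthrough for candidate-gene triage: one
#' latent cell population (log2 abundance SD 1) measured by four
#' candidate genes — GENE1 and GENE2 are ideal markers (unit slope, noise
#' SD 0.1), GENE3 is an independent noise gene, and GENE4 tracks the
#' population with slope 2, so it is strongly Pearson-correlated with the
#' true markers (similarity about 2*2/(1+4) = 0.8) yet cannot share a
#' cell type with them.  [selectMarkers()] on this scenario at thresholds
#' (0.6, 0.4) selects exactly GENE1 and GENE2.
#'
#' @param n Number of samples (default 500).
#' @param seed RNG seed (default 1).
#' @return A [TILSimulation-class].
#' @examples
#' sim <- simulateArchetypes(seed = 7)
#' sm <- similarityMatrix(simExpression(sim))
#' selectMarkers(sm, cellType = "demo")
#' @export
simulateArchetypes <- function(n = 500, seed = 1) {
  cfg <- simConfig(
    nSamples = n,
    cellTypes = data.frame(name = "target", log2_mean = 6, log2_sd = 1),
    genes = data.frame(
      symbol = c("GENE1", "GENE2", "GENE3", "GENE4"),
      role = c("pure", "pure", "noise", "slope"),
      cell_type = c("target", "target", "", "target"),
      constant = c(4, 2, 64, 1),
      noise_sd = c(0.1, 0.1, 1, 0.1),
      gamma = c(NA, NA, NA, 2),
      stringsAsFactors = FALSE),
    infiltrateLoading = 0,
    seed = seed)
  simulateDataset(cfg)
}
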