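# shared test helpers: tiny constructors and independent oracles

# quick expression object from a matrix-like spec
mkExpr <- function(values, scale = "log2", genes = NULL, samples = NULL) {
  values <- as.matrix(values)
  if (!is.null(genes)) rownames(values) <- genes
  if (!is.null(samples)) colnames(values) <- samples
  if (is.null(rownames(values)))
    rownames(values) <- paste0("G", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  TILExpression(values, scale = scale)
}

# brute-force similarity oracle: explicit sums, no shared code path
oracleSimilarity <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  vx <- sxx / (n - 1); vy <- syy / (n - 1)
  sxy / (((n - 1) / 2) * (vx + vy))
}

# closed-form one-way ANOVA (method of moments) variance components,
# balanced designs only
momComponents <- function(values, sample) {
  sample <- factor(sample)
  k <- nlevels(sample)
  r <- unique(table(sample))
  stopifnot(length(r) == 1L)
  means <- tapply(values, sample, mean)
  MSB <- r * stats::var(as.vector(means))
  MSW <- sum(tapply(values, sample,
                    function(x) sum((x - mean(x))^2))) / (k * (r - 1))
  list(between = (MSB - MSW) / r, within = MSW)
}
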