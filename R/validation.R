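#' Mean-centered root mean squared error between two platforms
#'
#' Each platform reports cell abundance on its own scale, so the two
#' measurement vectors are mean-centered independently before taking the
#' root mean squared difference of matching pairs.  The result is in log2
#' units when the inputs are; it is invariant to adding a constant to
#' either platform and symmetric in the platforms.
#'
#' @param a,b Numeric vectors of matched measurements (log2 scale),
#'   aligned by sample; length >= 2.
#' @return A non-negative number.
#' @examples
#' centeredRMSE(c(1, 2, 3), c(2, 3, 4))   # 0: pure shift
#' @export
centeredRMSE <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  if (length(a) < 2L) stop("at least 2 matched pairs are required")
  d <- (a - mean(a)) - (b - mean(b))
  sqrt(mean(d^2))
}

#' Concordance between two measurement platforms
#'
#' Standard cross-platform agreement summary for matched cell-abundance
#' measurements: Pearson correlation, the least-squares slope of `b` on
#' `a`, and the mean-centered RMSE.  A slope near 1 on log2 data means a
#' 2-fold change on one platform predicts a 2-fold change on the other —
#' stronger evidence of agreement than correlation alone.
#'
#' @param a,b Numeric vectors of matched log2-scale measurements; length
#'   >= 3, both with positive variance.
#' @return A list with elements `r`, `slope`, `rmse` and `n`.
#' @export
platformConcordance <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  if (length(a) < 3L) stop("at least 3 matched pairs are required")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("zero variance in one of the platforms")
  list(r = stats::cor(a, b),
       slope = unname(stats::coef(stats::lm(b ~ a))[2L]),
       rmse = centeredRMSE(a, b),
       n = length(a))
}

#' Replicate reproducibility via variance components
#'
#' Decomposes replicate cell-score measurements into between-sample and
#' residual (technical) variance with a one-way random-effects model —
#' a linear mixed model with sample identity as the random effect, fit by
#' REML — and reports the proportion of variance due to noise,
#' `residual / (residual + between)`.  On balanced designs the REML fit
#' coincides with the classical one-way ANOVA method-of-moments estimates
#' whenever those are non-negative.
#'
#' @param values Numeric vector of replicate cell scores (log2 scale).
#' @param sample Sample identifier for each value (same length).
#' @return A [VarianceComponents-class].
#' @details At least two samples, with replication in at least one, are
#'   required.  Two degenerate cases are resolved by convention without
#'   fitting: all values identical (both components 0, noise proportion
#'   0) and replicates identical within every sample (residual 0, noise
#'   proportion 0, between-sample variance from the sample means).  A
#'   between-sample component estimated at the zero boundary is flagged
#'   as truncated.
#' @export
noiseVariance <- function(values, sample) {
  if (length(values) != length(sample))
    stop("'values' and 'sample' must have equal length")
  sample <- factor(sample)
  if (nlevels(sample) < 2L) stop("at least 2 samples are required")
  reps <- table(sample)
  if (all(reps < 2L)) stop("no replication: every sample has one value")

  mk <- function(between, resid, truncated = FALSE) {
    tot <- between + resid
    new("VarianceComponents", betweenVar = between, residVar = resid,
        noiseProportion = if (tot == 0) 0 else resid / tot,
        residSD = sqrt(resid), nSamples = nlevels(sample),
        nReplicates = as.integer(reps), truncated = truncated)
  }

  withinVar <- tapply(values, sample, stats::var)
  if (all(is.na(withinVar) | withinVar == 0)) {
    # replicates identical within each sample: no residual noise
    means <- tapply(values, sample, mean)
    return(mk(stats::var(as.vector(means)), 0))
  }

  df <- data.frame(value = values, sample = sample)
  fit <- lme4::lmer(value ~ 1 + (1 | sample), data = df, REML = TRUE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore",
                      calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  between <- vc$vcov[vc$grp == "sample"]
  resid <- vc$vcov[vc$grp == "Residual"]
  mk(max(between, 0), resid, truncated = between <= 0)
}
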