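#' @include AllClasses.R AllGenerics.R
NULL

# core OLS + Wald machinery shared by the fitDecline methods
.fitDeclineCore <- function(tDays, y) {
  keep <- is.finite(tDays) & is.finite(y)
  tDays <- tDays[keep]
  y <- y[keep]
  n <- length(y)
  if (n < 3) stop("at least 3 finite points are required")
  if (stats::var(tDays) <= 0) stop("zero variance in the time regressor")
  if (diff(range(y)) < 1e-12 * max(1, abs(y[1]))) {
    warning("constant scores: degenerate fit (slope 0, R^2 0, p 1)")
    return(new("DeclineFit", slope = 0, intercept = y[1], rSquared = 0,
               pValue = 1, slopeSE = NA_real_, nPoints = as.integer(n),
               degenerate = TRUE))
  }
  fit <- stats::lm(y ~ tDays)
  cf <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  if (rss < 1e-12 * tss) {
    warning("perfect fit: residual variance is zero (p reported as 0)")
    return(new("DeclineFit", slope = unname(cf[2]),
               intercept = unname(cf[1]), rSquared = 1, pValue = 0,
               slopeSE = 0, nPoints = as.integer(n), degenerate = TRUE))
  }
  sm <- summary(fit)$coefficients
  new("DeclineFit", slope = unname(cf[2]), intercept = unname(cf[1]),
      rSquared = 1 - rss / tss, pValue = unname(sm[2, 4]),
      slopeSE = unname(sm[2, 2]), nPoints = as.integer(n),
      degenerate = FALSE)
}

#' @describeIn fitDecline Times (days) as a numeric vector, with `values`
#'   the movement scores.
#' @param values Movement scores (same length as the time vector).
#' @export
setMethod("fitDecline", "numeric", function(object, values, ...) {
  .fitDeclineCore(object, values)
})

#' @describeIn fitDecline Block totals against block start age (days).
#' @export
setMethod("fitDecline", "BlockSeries", function(object, ...) {
  .fitDeclineCore(object@blockStart / 86400, object@total)
})

#' @describeIn fitDecline Protocol scores against timepoint age (days).
#' @export
setMethod("fitDecline", "ScoreSeries", function(object, ...) {
  .fitDeclineCore(object@t / 86400, object@score)
})

#' Classify a fit as a detected movement decline
#'
#' Decline is detected iff the slope is negative and the Wald p-value is
#' below `alpha / nComparisons` (Bonferroni).  A significant positive slope
#' is reported but never classed as decline.
#'
#' @param fit A [DeclineFit-class].
#' @param alpha Significance level (default 0.05).
#' @param nComparisons Bonferroni divisor (default 1, i.e. per-individual
#'   tests; set to the cohort size for cohort-level correction).
#' @return `"detected"` or `"not_detected"`.
#' @examples
#' fit <- fitDecline(c(0, 1, 2, 3), values = c(60, 52, 45, 38))
#' classifyDecline(fit)
#' @export
classifyDecline <- function(fit, alpha = 0.05, nComparisons = 1) {
  stopifnot(is(fit, "DeclineFit"))
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (nComparisons < 1) stop("'nComparisons' must be >= 1")
  if (fit@slope < 0 && fit@pValue < alpha / nComparisons) "detected"
  else "not_detected"
}

#' Biological-interest flag for a correlation or decline fit
#'
#' A relationship is flagged as of biological interest when it is both
#' statistically significant (Bonferroni-corrected p below `alpha`) and
#' explains more than `r2Min` of the variance; weaker correlations,
#' regardless of p-value, capture little of the biological effect.
#'
#' @param fit A [DeclineFit-class].
#' @param alpha Significance level.
#' @param nComparisons Bonferroni divisor.
#' @param r2Min Minimum coefficient of determination (default 0.10).
#' @return Logical.
#' @export
biologicalInterest <- function(fit, alpha = 0.05, nComparisons = 1,
                               r2Min = 0.10) {
  stopifnot(is(fit, "DeclineFit"))
  fit@pValue < alpha / nComparisons && fit@rSquared > r2Min
}

# retained displacement entries grouped into blocks, as used by both
# blockTotals() and the within-block bootstrap
.blockEntries <- function(ds, blockDuration) {
  idx <- floor(ds@t / blockDuration + 1e-9)
  blocks <- min(0, min(idx)):max(idx)
  keep <- !ds@excluded
  entries <- lapply(blocks, function(b) ds@d[keep & idx == b])
  list(entries = entries, start = blocks * blockDuration)
}

#' Within-block bootstrap CI of the movement decline rate
#'
#' For each block, the individual's retained displacement entries within
#' that block are resampled with replacement (preserving the block's entry
#' count) and summed to a resampled block total; the decline rate is the
#' OLS slope of the resampled totals against block start age.  Repeating
#' `nBoot` times yields a percentile confidence interval.  A block with no
#' retained entries contributes a resampled total of 0 (with a warning).
#'
#' @param ds A [DisplacementSeries-class].
#' @param blockDuration Block length (s); default 3 h.
#' @param nBoot Bootstrap replicates (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the resampling.
#' @return A [BootstrapCI-class]; units mm per block per day.
#' @examples
#' traj <- simulateIndividual(generatorConfig(nDays = 2), 0)
#' bootstrapDeclineCI(displacementSeries(traj, 60), nBoot = 200, seed = 1)
#' @export
bootstrapDeclineCI <- function(ds, blockDuration = 10800, nBoot = 10000,
                               level = 0.95, seed = 1L) {
  be <- .blockEntries(ds, blockDuration)
  nb <- length(be$entries)
  if (nb < 3) stop("at least 3 blocks are required")
  empty <- vapply(be$entries, length, integer(1)) == 0L
  if (any(empty))
    warning(sprintf(
      "%d block(s) have no retained entries; their resampled totals are 0",
      sum(empty)))
  tDays <- be$start / 86400
  origTotals <- vapply(be$entries, sum, numeric(1)) / 1000
  point <- unname(stats::coef(stats::lm(origTotals ~ tDays))[2])
  slopes <- .withSeed(as.integer(seed),
                      bootSlopesCpp(be$entries, tDays, as.integer(nBoot)))
  qs <- unname(stats::quantile(slopes, c((1 - level) / 2,
                                         1 - (1 - level) / 2)))
  new("BootstrapCI", pointEstimate = point, lower = qs[1], upper = qs[2],
      level = level, nBoot = as.integer(nBoot), seed = as.integer(seed))
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param values Numeric vector (>= 2 values, positive mean).
#' @return Dimensionless CV.
#' @examples
#' coefficientOfVariation(c(40, 60, 80))
#' @export
coefficientOfVariation <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("at least 2 values are required")
  m <- mean(values)
  if (m <= 0) stop("mean must be positive")
  stats::sd(values) / m
}

#' Pairwise day-to-day correlation matrix
#'
#' Entry (i, j) is the squared Pearson correlation across individuals of
#' day-i versus day-j movement totals; the diagonal is 1.  Pairs with fewer
#' than 3 complete observations are flagged missing (NA).
#'
#' @param daily Numeric matrix, individuals x days (columns are days).
#' @return Symmetric day x day matrix of R^2 values.
#' @examples
#' m <- cbind(day1 = c(10, 20, 30), day2 = c(12, 19, 33))
#' dayCorrelationMatrix(m)
#' @export
dayCorrelationMatrix <- function(daily) {
  daily <- as.matrix(daily)
  if (nrow(daily) < 3) stop("at least 3 individuals are required")
  nd <- ncol(daily)
  out <- matrix(NA_real_, nd, nd,
                dimnames = list(colnames(daily), colnames(daily)))
  diag(out) <- 1
  for (i in seq_len(nd)) for (j in seq_len(nd)) {
    if (j <= i) next
    ok <- is.finite(daily[, i]) & is.finite(daily[, j])
    if (sum(ok) < 3) next
    if (stats::sd(daily[ok, i]) == 0 || stats::sd(daily[ok, j]) == 0) next
    r <- stats::cor(daily[ok, i], daily[ok, j])
    out[i, j] <- out[j, i] <- r^2
  }
  out
}

#' Animal-subset bootstrap CI of a squared Pearson correlation
#'
#' Each replicate draws `floor(fraction * n_animals)` animals without
#' replacement, pools their (x, y) pairs and computes the squared Pearson
#' correlation; the CI is the percentile interval of the replicates.
#'
#' @param x,y Paired observations.
#' @param group Animal identifier per pair (>= 5 distinct animals).
#' @param fraction Fraction of animals per replicate, in (0, 1]; default
#'   0.9.
#' @param nBoot Replicates (default 1000).
#' @param seed Integer seed.
#' @return A [BootstrapCI-class] for R^2.
#' @examples
#' g <- rep(1:6, each = 10)
#' x <- rnorm(60); y <- x + rnorm(60)
#' bootstrapR2CI(x, y, g, nBoot = 200, seed = 1)
#' @export
bootstrapR2CI <- function(x, y, group, fraction = 0.9, nBoot = 1000,
                          seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
  if (length(x) != length(y) || length(x) != length(group))
    stop("'x', 'y' and 'group' must have equal length")
  groups <- unique(group)
  if (length(groups) < 5) stop("at least 5 animals are required")
  point <- stats::cor(x, y)^2
  m <- max(1L, floor(fraction * length(groups)))
  reps <- .withSeed(as.integer(seed), {
    vapply(seq_len(nBoot), function(i) {
      g <- sample(groups, m, replace = FALSE)
      sel <- group %in% g
      if (stats::sd(x[sel]) == 0 || stats::sd(y[sel]) == 0) return(0)
      stats::cor(x[sel], y[sel])^2
    }, numeric(1))
  })
  qs <- unname(stats::quantile(reps, c(0.025, 0.975)))
  new("BootstrapCI", pointEstimate = point,
      lower = min(qs[1], point), upper = max(qs[2], point),
      level = 0.95, nBoot = as.integer(nBoot), seed = as.integer(seed))
}

#' Fidelity of protocol scores to the gold standard
#'
#' Squared Pearson correlation between a protocol's per-timepoint scores
#' and the gold-standard (1-fpm) movement totals over the matching periods:
#' each score timepoint is paired with the gold block containing it.
#' Constant scores (zero variance) carry no information about gold
#' movement and yield R^2 = 0 with a warning.
#'
#' @param gold A [BlockSeries-class] of gold-standard totals whose block
#'   duration matches the protocol's comparison period.
#' @param scoreSeries A [ScoreSeries-class].
#' @return Squared Pearson correlation (dimensionless).
#' @examples
#' traj <- simulateIndividual(generatorConfig(nDays = 1), 0)
#' gold <- blockTotals(displacementSeries(traj, 60), 10800)
#' protocolFidelity(gold, scoreHybrid(traj))
#' @export
protocolFidelity <- function(gold, scoreSeries) {
  stopifnot(is(gold, "BlockSeries"), is(scoreSeries, "ScoreSeries"))
  idx <- findInterval(scoreSeries@t + 1e-9, gold@blockStart)
  ok <- idx >= 1 & idx <= length(gold@total)
  g <- gold@total[idx[ok]]
  s <- scoreSeries@score[ok]
  if (length(s) < 3) stop("fewer than 3 paired points")
  if (stats::sd(s) == 0 || stats::sd(g) == 0) {
    warning("zero-variance input: R^2 defined as 0")
    return(0)
  }
  stats::cor(g, s)^2
}
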