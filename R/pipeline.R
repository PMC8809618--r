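#' @include AllClasses.R simulate.R motility.R protocols.R decline-stats.R io.R
NULL

#' Construct a pipeline configuration
#'
#' @param generator A [GeneratorConfig-class] (default
#'   `generatorConfig()`).
#' @param protocols List of [ProtocolSpec-class]; default the package's
#'   standard suite (snapshots at 2, 15 and 150 min; once- and twice-daily
#'   15-min video; the 7-image/3-min/3-h hybrid).
#' @param nIndividuals Cohort size (default 33).
#' @param alpha Significance level for decline classification.
#' @param nBoot Bootstrap replicates for per-individual decline CIs.
#' @param level Bootstrap CI level.
#' @param bonferroniCohort Bonferroni-correct decline tests by cohort size.
#' @param outputDir Output directory for [runPipeline()] tables.
#' @param logLevel `"info"` or `"quiet"`.
#' @return A validated [RunConfig-class].
#' @export
runConfig <- function(generator = generatorConfig(),
                      protocols = list(
                        singleSnapshotProtocol(120),
                        singleSnapshotProtocol(900),
                        singleSnapshotProtocol(9000),
                        dailyVideoProtocol(1),
                        dailyVideoProtocol(2),
                        hybridProtocol()),
                      nIndividuals = 33,
                      alpha = 0.05,
                      nBoot = 10000,
                      level = 0.95,
                      bonferroniCohort = FALSE,
                      outputDir = tempfile("wormMotility-run-"),
                      logLevel = "info") {
  new("RunConfig", generator = generator, protocols = protocols,
      nIndividuals = nIndividuals, alpha = alpha, nBoot = nBoot,
      level = level, bonferroniCohort = bonferroniCohort,
      outputDir = outputDir, logLevel = logLevel)
}

.log <- function(config, fmt, ...) {
  if (config@logLevel == "info")
    message(sprintf(paste0("[wormMotility] ", fmt), ...))
}

#' Headline cohort statistics from gold-standard scoring
#'
#' Runs the gold-standard scoring pipeline on a simulated (or real) cohort:
#' 1-fpm displacement series, 3-hour block totals, the group decline fit of
#' cohort-mean block totals against age, per-day totals with coefficients
#' of variation, the pairwise day-correlation matrix, per-individual
#' decline fits, and — when the trajectories carry sub-minute resolution —
#' the per-minute net-vs-total displacement correlation.
#'
#' @param cohort List of [Trajectory-class] objects.
#' @param alpha Significance level for the per-individual decline
#'   classification.
#' @param nComparisons Bonferroni divisor for that classification.
#' @param netTotalWindow Start/end time (s) of the window over which the
#'   per-minute net-vs-total R^2 is computed (default the 20 clean minutes
#'   after the first stimulus exclusion on day 1).
#' @return A list: `blockSeries` (per individual), `meanBlockTotals`,
#'   `groupFit` ([DeclineFit-class] of the cohort-mean block totals),
#'   `day0BlockMean`, `finalDayBlockMean`, `foldDecline`, `daily`
#'   (individuals x days matrix, mm), `dayCV`, `day1CVpct`,
#'   `dayCorrelation`, `individualFits`, `nDeclineDetected`,
#'   `netTotalR2`.
#' @examples
#' cohort <- simulateCohort(generatorConfig(nDays = 2), n = 4)
#' s <- cohortSummary(cohort)
#' s$day0BlockMean
#' @export
cohortSummary <- function(cohort, alpha = 0.05, nComparisons = 1,
                          netTotalWindow = c(1800, 3000)) {
  stopifnot(length(cohort) >= 1)
  bss <- lapply(cohort, function(tr)
    blockTotals(displacementSeries(tr, 60), 10800))
  nb <- min(vapply(bss, function(b) length(b@total), integer(1)))
  tot <- vapply(bss, function(b) b@total[seq_len(nb)], numeric(nb))
  starts <- bss[[1]]@blockStart[seq_len(nb)]
  meanTot <- rowMeans(tot)
  groupFit <- fitDecline(starts / 86400, values = meanTot)
  span <- max(starts) + 10800
  day0 <- starts < 86400
  final <- starts >= span - 86400
  day0Mean <- mean(tot[day0, ])
  finalMean <- mean(tot[final, ])
  daily <- t(vapply(cohort, function(tr) {
    dt <- dailyTotals(displacementSeries(tr, 60))
    dt$total_mm
  }, numeric(floor(span / 86400))))
  rownames(daily) <- vapply(cohort, individualId, character(1))
  colnames(daily) <- paste0("day", seq_len(ncol(daily)))
  dayCV <- apply(daily, 2, coefficientOfVariation)
  fits <- lapply(bss, fitDecline)
  detected <- vapply(fits, function(f)
    classifyDecline(f, alpha, nComparisons) == "detected", logical(1))
  r2 <- .netTotalR2(cohort, netTotalWindow)
  list(blockSeries = bss, meanBlockTotals = meanTot, blockStarts = starts,
       groupFit = groupFit, day0BlockMean = day0Mean,
       finalDayBlockMean = finalMean,
       foldDecline = day0Mean / finalMean, daily = daily, dayCV = dayCV,
       day1CVpct = 100 * dayCV[["day1"]],
       dayCorrelation = dayCorrelationMatrix(daily),
       individualFits = fits, nDeclineDetected = sum(detected),
       netTotalR2 = r2)
}

# pooled per-minute net vs total displacement R^2 over a clean window;
# needs sub-minute native resolution, else NA
.netTotalR2 <- function(cohort, window) {
  native <- .nativeInterval(cohort[[1]])
  if (native >= 60) return(NA_real_)
  nets <- numeric(0)
  tots <- numeric(0)
  mins <- seq(window[1], window[2] - 60, by = 60)
  for (tr in cohort) {
    for (m in mins) {
      sel <- which(tr@t >= m - 1e-9 & tr@t <= m + 60 + 1e-9)
      if (length(sel) < 2) next
      xx <- tr@x[sel]
      yy <- tr@y[sel]
      tots <- c(tots, sum(sqrt(diff(xx)^2 + diff(yy)^2)))
      nets <- c(nets, sqrt((xx[length(xx)] - xx[1])^2 +
                           (yy[length(yy)] - yy[1])^2))
    }
  }
  if (length(nets) < 3 || stats::sd(tots) == 0) return(NA_real_)
  stats::cor(nets, tots)^2
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort under the configured generator, scores it with the
#' gold-standard pipeline and the configured protocol suite, runs all
#' decline statistics, and writes the result tables (tab-separated, one
#' header line) plus a machine-readable JSON summary to the output
#' directory: `block_totals.tsv`, `decline_fits.tsv` (per-individual fit +
#' within-block bootstrap CI), `daily_totals.tsv`, `day_cv.tsv`,
#' `day_correlation.tsv`, `protocol_sweep.tsv`, `trajectories.tsv` +
#' `exclusions.tsv`, and `summary.json`.
#'
#' Reruns with an identical configuration produce byte-identical output.
#'
#' @param config A [RunConfig-class].
#' @param writeTrajectoryTable Also write the (large) per-frame trajectory
#'   table (default FALSE).
#' @return Invisibly, a list with the cohort, the [cohortSummary()]
#'   result, the bootstrap CIs, the protocol sweep table and the summary
#'   list.
#' @export
runPipeline <- function(config = runConfig(), writeTrajectoryTable = FALSE) {
  validObject(config)
  dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config@outputDir, f)
  gen <- config@generator
  .log(config, "simulating %d individuals (%g days, seed %d)",
       config@nIndividuals, gen@nDays, gen@seed)
  cohort <- simulateCohort(gen, config@nIndividuals)
  nComp <- if (config@bonferroniCohort) length(cohort) else 1
  .log(config, "gold-standard scoring and cohort statistics")
  sm <- cohortSummary(cohort, alpha = config@alpha, nComparisons = nComp)

  blockTab <- do.call(rbind, lapply(sm$blockSeries, function(b)
    data.frame(individual = b@individualId, block_start_s = b@blockStart,
               total_mm = b@total, n_contributing = b@nContributing)))
  .writeTsv(blockTab, out("block_totals.tsv"))

  .log(config, "per-individual decline fits and bootstrap CIs (%g reps)",
       config@nBoot)
  cis <- lapply(seq_along(cohort), function(i) {
    tr <- cohort[[i]]
    bootstrapDeclineCI(displacementSeries(tr, 60), 10800,
                       nBoot = config@nBoot, level = config@level,
                       seed = .individualSeed(gen@seed, i + 10000L))
  })
  fitTab <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    f <- sm$individualFits[[i]]
    ci <- cis[[i]]
    data.frame(individual = individualId(cohort[[i]]),
               slope_mm_per_block_day = f@slope,
               intercept_mm = f@intercept, r_squared = f@rSquared,
               p_value = f@pValue,
               ci_lower = ci@lower, ci_upper = ci@upper,
               decline_detected =
                 classifyDecline(f, config@alpha, nComp) == "detected",
               biological_interest = biologicalInterest(f, config@alpha,
                                                        nComp))
  }))
  .writeTsv(fitTab, out("decline_fits.tsv"))

  dailyTab <- data.frame(individual = rep(rownames(sm$daily),
                                          ncol(sm$daily)),
                         day = rep(seq_len(ncol(sm$daily)),
                                   each = nrow(sm$daily)),
                         total_mm = as.vector(sm$daily))
  .writeTsv(dailyTab, out("daily_totals.tsv"))
  .writeTsv(data.frame(day = seq_along(sm$dayCV), cv = sm$dayCV),
            out("day_cv.tsv"))
  corTab <- as.data.frame(sm$dayCorrelation)
  corTab <- cbind(day = rownames(corTab), corTab)
  .writeTsv(corTab, out("day_correlation.tsv"))

  .log(config, "protocol sweep (%d protocols)", length(config@protocols))
  sweep <- protocolSweep(cohort, config@protocols, alpha = config@alpha,
                         nComparisons = nComp)
  .writeTsv(sweep, out("protocol_sweep.tsv"))

  if (writeTrajectoryTable)
    writeTrajectories(cohort, out("trajectories.tsv"),
                      out("exclusions.tsv"))

  protoAgg <- lapply(split(sweep, sweep$protocol), function(s) list(
    mean_fidelity_r2 = mean(s$fidelity_r2, na.rm = TRUE),
    n_decline_detected = sum(s$decline_detected, na.rm = TRUE)))
  summary <- list(
    schema_version = "1.0",
    seed = gen@seed,
    n_individuals = length(cohort),
    group_decline_rate_mm_per_block_day = -sm$groupFit@slope,
    group_fit_r_squared = sm$groupFit@rSquared,
    group_fit_p_value = sm$groupFit@pValue,
    day0_block_mean_mm = sm$day0BlockMean,
    final_day_block_mean_mm = sm$finalDayBlockMean,
    fold_decline = sm$foldDecline,
    day1_cv_pct = sm$day1CVpct,
    day_cv = as.list(sm$dayCV),
    net_vs_total_r2 = sm$netTotalR2,
    n_decline_detected_gold = sm$nDeclineDetected,
    protocols = protoAgg)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  .log(config, "done; outputs in %s", config@outputDir)
  invisible(list(cohort = cohort, summary = sm, bootstrapCIs = cis,
                 protocolSweep = sweep, json = summary))
}
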