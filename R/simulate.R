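#' @include AllClasses.R
NULL

# Block total (mm per 3-h block) that the base behavioural-state
# parameterisation produces at unit activity; the activity multiplier of an
# individual at age t is (meanDay0BlockTotal * L_i - rate_i * (t - 0.5)) /
# .calibRef, so with the shipped defaults the cohort-mean day-0 block total
# lands on meanDay0BlockTotal.
.calibRef <- 60

# 30-minute post-stimulus exclusion, in seconds
.stimExclusion <- 1800

#' Construct a generator configuration
#'
#' Returns a [GeneratorConfig-class] whose defaults are the package's
#' calibrated study conditions: a 0.88-mm-radius arena observed for 6 days
#' of adulthood at 1 frame/s, a cohort-mean movement level of 60 mm per
#' 3-hour block during day 0 declining by 7.8 mm per block per day, a
#' stimulus every 3 h (each emitting a 30-min exclusion window), and
#' variability components tuned so that a 33-individual cohort shows a
#' day-1 coefficient of variation near 27% and a per-minute net-vs-total
#' displacement R^2 near 0.6.
#'
#' @param arenaRadius Arena radius (um).
#' @param nDays Observation span (days of adulthood).
#' @param frameInterval Native sampling interval (s).
#' @param meanDay0BlockTotal Target cohort-mean day-0 3-h block total (mm).
#' @param populationDeclineRate Population mean decline (mm/block/day; a
#'   positive number, applied as a negative slope).
#' @param individualRateSd Between-individual SD of the decline rate;
#'   individual rates are redrawn until non-negative so every individual
#'   declines.
#' @param individualLevelSd SD of the lognormal persistent
#'   between-individual activity multiplier.
#' @param dayLevelVolatility SD of the lognormal per-(individual, day)
#'   activity multiplier.
#' @param intradayVolatility SD of the lognormal Ornstein-Uhlenbeck
#'   within-day activity modulation; produces the hours-scale activity
#'   bouts that make brief daily observation windows under-represent
#'   whole-day movement.
#' @param intradayTimescale Correlation time of that modulation (s).
#' @param stateTransitionRates Named per-second probabilities
#'   (`roamToDwell`, `dwellToRoam`, `dwellToQuiescent`, `quiescentToDwell`);
#'   `dwellToRoam` is multiplied by the age-dependent activity factor.
#' @param activeSpeedScale Mean roaming speed draw (um/s).
#' @param dwellSpeedFraction Dwelling jitter speed relative to
#'   `activeSpeedScale`.
#' @param turningKappa Heading-persistence concentration while roaming.
#' @param edgeAttractionStrength Radial bias toward the edge annulus.
#' @param edgeRingFraction Preferred annulus radius / arena radius.
#' @param stimTimes Stimulation times (s); default every 3 h across the
#'   span.  Only effect: a 30-min exclusion window after each.
#' @param seed Integer root seed.
#' @return A validated [GeneratorConfig-class].
#' @examples
#' cfg <- generatorConfig(nDays = 1, seed = 7)
#' traj <- simulateIndividual(cfg, 0)
#' @export
generatorConfig <- function(arenaRadius = 880,
                            nDays = 6,
                            frameInterval = 1,
                            meanDay0BlockTotal = 60,
                            populationDeclineRate = 7.8,
                            individualRateSd = 2.6,
                            individualLevelSd = 0.16,
                            dayLevelVolatility = 0.20,
                            intradayVolatility = 0.30,
                            intradayTimescale = 7200,
                            stateTransitionRates = c(
                              roamToDwell = 0.012,
                              dwellToRoam = 0.01467,
                              dwellToQuiescent = 0.002,
                              quiescentToDwell = 0.0015),
                            activeSpeedScale = 110,
                            dwellSpeedFraction = 0.05,
                            turningKappa = 6,
                            edgeAttractionStrength = 1.0,
                            edgeRingFraction = 0.8,
                            stimTimes = NULL,
                            seed = 1L) {
  if (is.null(stimTimes))
    stimTimes <- seq(0, nDays * 86400, by = 10800)
  new("GeneratorConfig",
      arenaRadius = arenaRadius, nDays = nDays,
      frameInterval = frameInterval,
      meanDay0BlockTotal = meanDay0BlockTotal,
      populationDeclineRate = populationDeclineRate,
      individualRateSd = individualRateSd,
      individualLevelSd = individualLevelSd,
      dayLevelVolatility = dayLevelVolatility,
      intradayVolatility = intradayVolatility,
      intradayTimescale = intradayTimescale,
      stateTransitionRates = stateTransitionRates,
      activeSpeedScale = activeSpeedScale,
      dwellSpeedFraction = dwellSpeedFraction,
      turningKappa = turningKappa,
      edgeAttractionStrength = edgeAttractionStrength,
      edgeRingFraction = edgeRingFraction,
      stimTimes = stimTimes, seed = as.integer(seed))
}

# deterministic substream seed for (root seed, individual index)
.individualSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(index) * 7919 + 12345) %%
             2147483629)
}

# evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate one individual's trajectory
#'
#' Draws the individual's persistent activity level (lognormal), decline
#' rate (normal around the population rate, redrawn until non-negative so
#' the slope of expected movement is never positive) and per-day volatility
#' factors, then runs the three-state (roaming / dwelling / quiescent)
#' per-second movement model inside the circular arena.  Aging enters as a
#' linear-in-age multiplier on the dwell-to-roam entry probability, anchored
#' so the day-0 mean block total matches the configuration.  A 30-minute
#' exclusion window is emitted after every stimulus time.
#'
#' The individual's random substream is derived from `(seed,
#' individualIndex)`, so cohorts are reproducible and order-independent,
#' and the caller's RNG state is left untouched.
#'
#' @param config A [GeneratorConfig-class].
#' @param individualIndex Zero-based individual index.
#' @return A [Trajectory-class] spanning `nDays` at `frameInterval`
#'   resolution.
#' @examples
#' traj <- simulateIndividual(generatorConfig(nDays = 1), 0)
#' traj
#' @export
simulateIndividual <- function(config, individualIndex) {
  validObject(config)
  if (length(individualIndex) != 1L || is.na(individualIndex) ||
      individualIndex < 0 || individualIndex != round(individualIndex))
    stop("'individualIndex' must be a single non-negative integer")
  dt <- config@frameInterval
  span <- config@nDays * 86400
  nSteps <- round(span / dt)
  rates <- config@stateTransitionRates
  dseed <- .individualSeed(config@seed, individualIndex)
  sdL <- config@individualLevelSd
  sdV <- config@dayLevelVolatility
  .withSeed(dseed, {
    L <- stats::rlnorm(1, meanlog = -sdL^2 / 2, sdlog = sdL)
    rate <- stats::rnorm(1, config@populationDeclineRate,
                         config@individualRateSd)
    tries <- 0L
    while (rate < 0 && tries < 1000L) {
      rate <- stats::rnorm(1, config@populationDeclineRate,
                           config@individualRateSd)
      tries <- tries + 1L
    }
    rate <- max(rate, 0)
    nDaysInt <- max(1L, ceiling(config@nDays))
    V <- stats::rlnorm(nDaysInt, meanlog = -sdV^2 / 2, sdlog = sdV)
    tD <- (0:(nSteps - 1L)) * dt / 86400
    dayIdx <- pmin(floor(tD), nDaysInt - 1L) + 1L
    f <- pmax(0, (config@meanDay0BlockTotal * L - rate * (tD - 0.5)) /
                .calibRef) * V[dayIdx]
    # hours-scale activity bouts: mean-one lognormal Ornstein-Uhlenbeck
    # modulation sampled on a minute grid and expanded to frame resolution
    sdG <- config@intradayVolatility
    if (sdG > 0) {
      grid <- 60
      nG <- ceiling(nSteps * dt / grid)
      a <- exp(-grid / config@intradayTimescale)
      z <- stats::rnorm(nG)
      g <- numeric(nG)
      g[1] <- sdG * z[1]
      for (k in seq_len(nG - 1L))
        g[k + 1L] <- a * g[k] + sdG * sqrt(1 - a^2) * z[k + 1L]
      mod <- exp(g)
      # normalise to mean one within each day so the modulation reshapes
      # when movement happens within a day without changing day totals
      gDay <- pmin(floor((seq_len(nG) - 1L) * grid / 86400), nDaysInt - 1L)
      dayMeans <- tapply(mod, gDay, mean)
      mod <- mod / as.numeric(dayMeans[as.character(gDay)])
      f <- f * mod[pmin(floor((0:(nSteps - 1L)) * dt / grid), nG - 1L) + 1L]
    }
    # aging acts as a linear multiplier on roaming occupancy: invert the
    # dwell<->roam balance so that target occupancy is proportional to f
    # (a raw multiplier on the entry probability would saturate instead)
    pdr <- rates[["dwellToRoam"]]
    prd <- rates[["roamToDwell"]]
    if (pdr > 0 && prd > 0) {
      occ1 <- pdr / (pdr + prd)
      occ <- pmin(occ1 * f, 0.95)
      f <- (prd * occ / (1 - occ)) / pdr
    }
    r0 <- config@arenaRadius * sqrt(stats::runif(1))
    th0 <- stats::runif(1) * 2 * pi
    pos <- simCoreCpp(
      nSteps = nSteps, dt = dt, arenaR = config@arenaRadius,
      activity = f,
      pRoamToDwell = rates[["roamToDwell"]],
      pDwellToRoam = rates[["dwellToRoam"]],
      pDwellToQuiescent = rates[["dwellToQuiescent"]],
      pQuiescentToDwell = rates[["quiescentToDwell"]],
      speedScale = config@activeSpeedScale,
      dwellSpeedFrac = config@dwellSpeedFraction,
      kappa = config@turningKappa,
      edgePull = config@edgeAttractionStrength,
      edgeRadiusFrac = config@edgeRingFraction,
      maxSpeed = 500,
      x0 = r0 * cos(th0), y0 = r0 * sin(th0),
      heading0 = stats::runif(1) * 2 * pi)
    stim <- config@stimTimes[config@stimTimes >= 0 &
                             config@stimTimes <= span]
    ew <- if (length(stim))
      cbind(start = stim, end = pmin(stim + .stimExclusion, span))
    else matrix(numeric(0), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
    new("Trajectory",
        individualId = sprintf("ind%03d", individualIndex),
        t = (0:nSteps) * dt, x = pos[, 1], y = pos[, 2],
        arenaRadius = config@arenaRadius, excludedWindows = ew)
  })
}

#' Simulate a cohort of trajectories
#'
#' @param config A [GeneratorConfig-class].
#' @param n Cohort size (default 33 individuals).
#' @return List of `n` [Trajectory-class] objects with distinct,
#'   reproducible per-individual substreams; element `i` equals
#'   `simulateIndividual(config, i - 1)`.
#' @examples
#' cohort <- simulateCohort(generatorConfig(nDays = 1), n = 2)
#' length(cohort)
#' @export
simulateCohort <- function(config, n = 33) {
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be >= 1")
  lapply(seq_len(n) - 1L, function(i) simulateIndividual(config, i))
}
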