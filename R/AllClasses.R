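#' @import methods
NULL

#' Configuration of the synthetic trajectory generator
#'
#' Holds every tunable of the stochastic movement model: arena geometry,
#' observation span, the calibration of population mean activity and its
#' age-related decline, between-individual and day-to-day variability, the
#' behavioural-state machinery (roaming / dwelling / quiescent transition
#' probabilities, roaming speed scale, directional persistence), the
#' edge-attraction bias, the stimulus schedule (used only to emit 30-minute
#' exclusion windows) and the root seed.
#'
#' Units: lengths in micrometres, durations in seconds, block totals in mm
#' per 3-hour block, decline rates in mm per 3-hour block per day of
#' adulthood.  `meanDay0BlockTotal` is the target cohort-mean 3-hour block
#' total during the first 24 h of adulthood; `populationDeclineRate` is the
#' (positive) population mean rate at which that level falls per day.
#'
#' @slot arenaRadius Arena radius in um.
#' @slot nDays Observation span in days of adulthood.
#' @slot frameInterval Native sampling interval in seconds.
#' @slot meanDay0BlockTotal Target day-0 cohort mean 3-h block total (mm).
#' @slot populationDeclineRate Population mean decline (mm/3-h block/day).
#' @slot individualRateSd Between-individual SD of the decline rate.
#' @slot individualLevelSd SD of the lognormal between-individual baseline
#'   activity multiplier (dimensionless).
#' @slot dayLevelVolatility SD of the lognormal per-day activity multiplier
#'   (dimensionless); controls how weakly day totals persist day-to-day.
#' @slot intradayVolatility SD of the lognormal Ornstein-Uhlenbeck
#'   within-day activity modulation (dimensionless); drives hours-scale
#'   activity bouts so short observation windows under-represent whole-day
#'   movement.
#' @slot intradayTimescale Correlation time of that modulation (s).
#' @slot stateTransitionRates Named per-second transition probabilities:
#'   `roamToDwell`, `dwellToRoam`, `dwellToQuiescent`, `quiescentToDwell`.
#' @slot activeSpeedScale Mean roaming speed draw (um/s).
#' @slot dwellSpeedFraction Dwelling jitter speed as a fraction of
#'   `activeSpeedScale`.
#' @slot turningKappa Directional-persistence concentration of the roaming
#'   heading (larger = straighter paths).
#' @slot edgeAttractionStrength Strength of the radial bias toward the edge
#'   annulus (dimensionless; 0 disables).
#' @slot edgeRingFraction Radius of the preferred annulus as a fraction of
#'   the arena radius.
#' @slot stimTimes Stimulation times (s); each emits a 30-minute exclusion
#'   window starting at the stimulus.
#' @slot seed Integer root seed; per-individual substreams are derived from
#'   (seed, individual index).
#' @seealso [generatorConfig()], [simulateIndividual()], [simulateCohort()]
#' @export
setClass("GeneratorConfig",
  representation(
    arenaRadius = "numeric",
    nDays = "numeric",
    frameInterval = "numeric",
    meanDay0BlockTotal = "numeric",
    populationDeclineRate = "numeric",
    individualRateSd = "numeric",
    individualLevelSd = "numeric",
    dayLevelVolatility = "numeric",
    intradayVolatility = "numeric",
    intradayTimescale = "numeric",
    stateTransitionRates = "numeric",
    activeSpeedScale = "numeric",
    dwellSpeedFraction = "numeric",
    turningKappa = "numeric",
    edgeAttractionStrength = "numeric",
    edgeRingFraction = "numeric",
    stimTimes = "numeric",
    seed = "integer"
  )
)

.rateNames <- c("roamToDwell", "dwellToRoam", "dwellToQuiescent",
                "quiescentToDwell")

setValidity("GeneratorConfig", function(object) {
  msgs <- character()
  chk1 <- function(x, nm) {
    if (length(slot(object, nm)) != 1L || !is.finite(slot(object, nm)))
      msgs <<- c(msgs, sprintf("'%s' must be a single finite number", nm))
  }
  for (nm in c("arenaRadius", "nDays", "frameInterval",
               "meanDay0BlockTotal", "populationDeclineRate",
               "individualRateSd", "individualLevelSd", "dayLevelVolatility",
               "intradayVolatility", "intradayTimescale",
               "activeSpeedScale", "dwellSpeedFraction", "turningKappa",
               "edgeAttractionStrength", "edgeRingFraction")) chk1(NULL, nm)
  if (length(msgs)) return(msgs)
  if (object@arenaRadius <= 0) msgs <- c(msgs, "'arenaRadius' must be > 0")
  if (object@frameInterval <= 0)
    msgs <- c(msgs, "'frameInterval' must be > 0")
  if (object@nDays <= 0) msgs <- c(msgs, "'nDays' must be > 0")
  for (nm in c("meanDay0BlockTotal", "populationDeclineRate",
               "individualRateSd", "individualLevelSd",
               "dayLevelVolatility", "intradayVolatility",
               "activeSpeedScale",
               "dwellSpeedFraction", "turningKappa",
               "edgeAttractionStrength"))
    if (slot(object, nm) < 0)
      msgs <- c(msgs, sprintf("'%s' must be >= 0", nm))
  if (object@intradayTimescale <= 0)
    msgs <- c(msgs, "'intradayTimescale' must be > 0")
  if (object@edgeRingFraction < 0 || object@edgeRingFraction > 1)
    msgs <- c(msgs, "'edgeRingFraction' must be in [0, 1]")
  if (!all(.rateNames %in% names(object@stateTransitionRates)))
    msgs <- c(msgs, sprintf("'stateTransitionRates' must be named %s",
                            paste(.rateNames, collapse = ", ")))
  else if (any(object@stateTransitionRates[.rateNames] < 0) ||
           any(object@stateTransitionRates[.rateNames] > 1))
    msgs <- c(msgs, "'stateTransitionRates' must be probabilities in [0, 1]")
  if (any(object@stimTimes < 0))
    msgs <- c(msgs, "'stimTimes' must be non-negative")
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "'seed' must be a single integer")
  if (length(msgs)) msgs else TRUE
})

#' A single individual's centroid trajectory
#'
#' Timestamped centroid positions of one animal in arena-centred
#' coordinates, together with the arena radius and the exclusion windows
#' (e.g. the 30 minutes following each light stimulus) that downstream
#' scoring must flag.
#'
#' @slot individualId Identifier.
#' @slot t Strictly increasing sample times (s since onset of adulthood).
#' @slot x,y Positions (um), arena-centred.
#' @slot arenaRadius Arena radius (um); all positions lie within it.
#' @slot excludedWindows Two-column matrix of (start, end) times (s).
#' @export
setClass("Trajectory",
  representation(
    individualId = "character",
    t = "numeric",
    x = "numeric",
    y = "numeric",
    arenaRadius = "numeric",
    excludedWindows = "matrix"
  )
)

setValidity("Trajectory", function(object) {
  msgs <- character()
  n <- length(object@t)
  if (length(object@x) != n || length(object@y) != n)
    msgs <- c(msgs, "'t', 'x' and 'y' must have equal length")
  if (n > 1 && any(diff(object@t) <= 0))
    msgs <- c(msgs, "'t' must be strictly increasing")
  if (length(object@arenaRadius) != 1L || object@arenaRadius <= 0)
    msgs <- c(msgs, "'arenaRadius' must be a single positive number")
  else if (length(object@x) == n && n > 0) {
    r2 <- object@x^2 + object@y^2
    if (any(r2 > object@arenaRadius^2 * (1 + 1e-9)))
      msgs <- c(msgs, "positions must satisfy sqrt(x^2+y^2) <= arenaRadius")
  }
  ew <- object@excludedWindows
  if (ncol(ew) != 2L)
    msgs <- c(msgs, "'excludedWindows' must have two columns (start, end)")
  else if (nrow(ew) > 0) {
    if (any(ew[, 2] < ew[, 1]))
      msgs <- c(msgs, "exclusion windows must have start <= end")
    if (n > 0 && (any(ew[, 1] < object@t[1] - 1e-9) ||
                  any(ew[, 2] > object@t[n] + 1e-9)))
      msgs <- c(msgs, "exclusion windows must lie within the observation span")
  }
  if (length(msgs)) msgs else TRUE
})

#' Per-interval displacement magnitudes derived from a trajectory
#'
#' `d[i]` is the Euclidean distance (um) between the retained positions at
#' `t[i]` and `t[i] + interval`.  Entries whose spanned time intersects an
#' exclusion window are flagged in `excluded`, never silently dropped.
#'
#' @slot individualId Identifier.
#' @slot interval Sampling interval (s).
#' @slot t Interval start times (s).
#' @slot d Displacement magnitudes (um), all >= 0.
#' @slot excluded Logical flag per entry.
#' @export
setClass("DisplacementSeries",
  representation(
    individualId = "character",
    interval = "numeric",
    t = "numeric",
    d = "numeric",
    excluded = "logical"
  )
)

setValidity("DisplacementSeries", function(object) {
  msgs <- character()
  if (length(object@interval) != 1L || object@interval <= 0)
    msgs <- c(msgs, "'interval' must be a single positive duration")
  if (length(object@t) != length(object@d) ||
      length(object@d) != length(object@excluded))
    msgs <- c(msgs, "'t', 'd' and 'excluded' must have equal length")
  if (any(object@d < 0)) msgs <- c(msgs, "displacements must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Movement totals summed over fixed time blocks
#'
#' Non-excluded displacement entries summed within consecutive blocks
#' (default 3 h) tiling the observation span from t = 0, expressed in mm per
#' block.  `nContributing` records how many retained entries each block sum
#' is built from, so users can rescale for excluded time if they wish.
#'
#' @slot individualId Identifier.
#' @slot blockDuration Block length (s).
#' @slot blockStart Block start times (s).
#' @slot total Movement per block (mm).
#' @slot nContributing Retained displacement entries per block.
#' @export
setClass("BlockSeries",
  representation(
    individualId = "character",
    blockDuration = "numeric",
    blockStart = "numeric",
    total = "numeric",
    nContributing = "integer"
  )
)

setValidity("BlockSeries", function(object) {
  msgs <- character()
  if (length(object@blockDuration) != 1L || object@blockDuration <= 0)
    msgs <- c(msgs, "'blockDuration' must be a single positive duration")
  n <- length(object@blockStart)
  if (length(object@total) != n || length(object@nContributing) != n)
    msgs <- c(msgs, "'blockStart', 'total' and 'nContributing' must match")
  if (any(object@total < -1e-12)) msgs <- c(msgs, "totals must be >= 0")
  if (n > 1 && any(abs(diff(object@blockStart) - object@blockDuration) >
                   1e-6))
    msgs <- c(msgs, "blocks must tile the span without overlap")
  if (length(msgs)) msgs else TRUE
})

#' Declarative description of an image-acquisition protocol
#'
#' Describes one of the candidate acquisition schemes whose movement scores
#' are produced by subsampling a gold-standard trajectory: `single_snapshot`
#' (one image per timepoint, score = net displacement between consecutive
#' timepoints), `daily_video` (one or more 15-minute 1-fpm bouts per day,
#' score = summed within-bout displacement), `hybrid_multipass` (several
#' images at minutes-scale spacing per timepoint, score = summed
#' displacement across the bout), or `continuous` (the gold standard
#' itself).
#'
#' @slot kind One of `"single_snapshot"`, `"daily_video"`,
#'   `"twice_daily_video"`, `"hybrid_multipass"`, `"continuous"`.
#' @slot interTimepointInterval Snapshot spacing or bout spacing (s).
#' @slot imagesPerBout Images acquired per bout (hybrid).
#' @slot intraBoutSpacing Spacing between within-bout images (s).
#' @slot boutsPerDay Bouts per day (video protocols).
#' @slot boutDuration Video bout duration (s).
#' @seealso [singleSnapshotProtocol()], [dailyVideoProtocol()],
#'   [hybridProtocol()], [continuousProtocol()]
#' @export
setClass("ProtocolSpec",
  representation(
    kind = "character",
    interTimepointInterval = "numeric",
    imagesPerBout = "numeric",
    intraBoutSpacing = "numeric",
    boutsPerDay = "numeric",
    boutDuration = "numeric"
  )
)

.protocolKinds <- c("single_snapshot", "daily_video", "twice_daily_video",
                    "hybrid_multipass", "continuous")

setValidity("ProtocolSpec", function(object) {
  msgs <- character()
  if (length(object@kind) != 1L || !(object@kind %in% .protocolKinds))
    return(sprintf("'kind' must be one of: %s",
                   paste(.protocolKinds, collapse = ", ")))
  k <- object@kind
  if (k == "single_snapshot") {
    if (object@interTimepointInterval <= 0)
      msgs <- c(msgs, "snapshot interval must be positive")
  } else if (k %in% c("daily_video", "twice_daily_video")) {
    if (object@boutsPerDay < 1)
      msgs <- c(msgs, "'boutsPerDay' must be >= 1")
    if (object@boutDuration <= 0)
      msgs <- c(msgs, "'boutDuration' must be positive")
    if (object@boutDuration > 86400 / max(object@boutsPerDay, 1))
      msgs <- c(msgs, "'boutDuration' must fit within 24 h / boutsPerDay")
  } else if (k == "hybrid_multipass") {
    if (object@imagesPerBout < 2)
      msgs <- c(msgs, "'imagesPerBout' must be >= 2")
    if (object@intraBoutSpacing <= 0)
      msgs <- c(msgs, "'intraBoutSpacing' must be positive")
    if (object@interTimepointInterval <= 0)
      msgs <- c(msgs, "'interTimepointInterval' must be positive")
    if ((object@imagesPerBout - 1) * object@intraBoutSpacing >
        object@interTimepointInterval)
      msgs <- c(msgs,
        "(imagesPerBout - 1) * intraBoutSpacing must fit inside the inter-timepoint interval")
  }
  if (length(msgs)) msgs else TRUE
})

#' Per-timepoint movement scores under an acquisition protocol
#'
#' @slot individualId Identifier.
#' @slot protocol The [ProtocolSpec-class] that produced the scores.
#' @slot t Timepoint times (s); each score covers the period starting at its
#'   timepoint.
#' @slot score Movement score (mm per timepoint), >= 0.
#' @export
setClass("ScoreSeries",
  representation(
    individualId = "character",
    protocol = "ProtocolSpec",
    t = "numeric",
    score = "numeric"
  )
)

setValidity("ScoreSeries", function(object) {
  msgs <- character()
  if (length(object@t) != length(object@score))
    msgs <- c(msgs, "'t' and 'score' must have equal length")
  if (any(object@score < -1e-12)) msgs <- c(msgs, "scores must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Linear decline fit of movement against age
#'
#' Ordinary least-squares fit of movement scores against age in days, with
#' the two-sided Wald test of zero slope against the t reference
#' distribution.
#'
#' @slot slope Movement change per day (e.g. mm per 3-h block per day).
#' @slot intercept Fitted movement level at day 0.
#' @slot rSquared Coefficient of determination, in [0, 1].
#' @slot pValue Two-sided Wald p-value for slope = 0.
#' @slot slopeSE Standard error of the slope.
#' @slot nPoints Number of points fitted.
#' @slot degenerate TRUE when the fit was degenerate (constant response or a
#'   perfect fit), in which case `pValue` is a convention (1 or 0).
#' @seealso [fitDecline()], [classifyDecline()], [biologicalInterest()]
#' @export
setClass("DeclineFit",
  representation(
    slope = "numeric",
    intercept = "numeric",
    rSquared = "numeric",
    pValue = "numeric",
    slopeSE = "numeric",
    nPoints = "integer",
    degenerate = "logical"
  )
)

setValidity("DeclineFit", function(object) {
  msgs <- character()
  if (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9)
    msgs <- c(msgs, "'rSquared' must be in [0, 1]")
  if (object@pValue < 0 || object@pValue > 1)
    msgs <- c(msgs, "'pValue' must be in [0, 1]")
  if (object@nPoints < 3)
    msgs <- c(msgs, "'nPoints' must be >= 3 for a p-value to be emitted")
  if (length(msgs)) msgs else TRUE
})

#' Percentile bootstrap confidence interval
#'
#' @slot pointEstimate Statistic on the original data.
#' @slot lower,upper Percentile interval bounds.
#' @slot level Nominal coverage (default 0.95).
#' @slot nBoot Number of bootstrap replicates.
#' @slot seed Seed used for resampling.
#' @export
setClass("BootstrapCI",
  representation(
    pointEstimate = "numeric",
    lower = "numeric",
    upper = "numeric",
    level = "numeric",
    nBoot = "integer",
    seed = "integer"
  )
)

setValidity("BootstrapCI", function(object) {
  msgs <- character()
  if (object@lower > object@upper + 1e-12)
    msgs <- c(msgs, "'lower' must be <= 'upper'")
  if (object@level <= 0 || object@level >= 1)
    msgs <- c(msgs, "'level' must be in (0, 1)")
  if (object@nBoot < 1) msgs <- c(msgs, "'nBoot' must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' A synthetic or acquired brightfield arena image
#'
#' Single-channel 16-bit-range intensity grid with the optical scale and,
#' for synthetic frames, the generating lawn geometry.
#'
#' @slot pixels Numeric matrix of intensities in [0, 65535].
#' @slot pixelSize Length per pixel (um; default 1.3 = 6.5 um sensor pixel
#'   at 5x magnification).
#' @slot lawnCenter Lawn centre (um, image coordinates), length 2.
#' @slot lawnRadius Lawn radius (um).
#' @slot noiseSd Additive noise SD used at render time (intensity units).
#' @export
setClass("ArenaImage",
  representation(
    pixels = "matrix",
    pixelSize = "numeric",
    lawnCenter = "numeric",
    lawnRadius = "numeric",
    noiseSd = "numeric"
  )
)

setValidity("ArenaImage", function(object) {
  msgs <- character()
  if (nrow(object@pixels) < 1 || ncol(object@pixels) < 1)
    msgs <- c(msgs, "'pixels' must be non-empty")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msgs <- c(msgs, "'pixelSize' must be a single positive length")
  if (length(object@lawnCenter) != 2L)
    msgs <- c(msgs, "'lawnCenter' must have length 2")
  if (length(msgs)) return(msgs)
  if (object@lawnRadius > 0) {
    w <- ncol(object@pixels) * object@pixelSize
    h <- nrow(object@pixels) * object@pixelSize
    cx <- object@lawnCenter[1]
    cy <- object@lawnCenter[2]
    r <- object@lawnRadius
    if (cx - r < 0 || cx + r > w || cy - r < 0 || cy + r > h)
      msgs <- c(msgs, "lawn disc must lie fully inside the image")
  }
  if (length(msgs)) msgs else TRUE
})

#' Binary lawn mask with calibrated area
#'
#' @slot mask Logical pixel grid (TRUE = lawn).
#' @slot pixelSize Length per pixel (um).
#' @slot nFramesCombined Number of per-frame masks OR-combined.
#' @slot area Lawn area in mm^2, equal to
#'   `sum(mask) * pixelSize^2 / 1e6`.
#' @export
setClass("LawnMask",
  representation(
    mask = "matrix",
    pixelSize = "numeric",
    nFramesCombined = "integer",
    area = "numeric"
  )
)

setValidity("LawnMask", function(object) {
  msgs <- character()
  if (!is.logical(object@mask))
    msgs <- c(msgs, "'mask' must be a logical matrix")
  else {
    a <- sum(object@mask) * object@pixelSize^2 / 1e6
    if (abs(a - object@area) > 1e-9 * max(1, a))
      msgs <- c(msgs, "'area' must equal true-pixel count * pixelSize^2 / 1e6")
  }
  if (object@nFramesCombined < 1)
    msgs <- c(msgs, "'nFramesCombined' must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' End-to-end pipeline configuration
#'
#' @slot generator A [GeneratorConfig-class].
#' @slot protocols List of [ProtocolSpec-class] objects to sweep.
#' @slot nIndividuals Cohort size.
#' @slot alpha Significance level for decline classification.
#' @slot nBoot Bootstrap replicates for per-individual decline CIs.
#' @slot level Bootstrap CI level.
#' @slot bonferroniCohort If TRUE, Bonferroni-correct per-individual decline
#'   tests by the cohort size; if FALSE (default) tests are per-individual.
#' @slot outputDir Output directory.
#' @slot logLevel One of "quiet", "info".
#' @export
setClass("RunConfig",
  representation(
    generator = "GeneratorConfig",
    protocols = "list",
    nIndividuals = "numeric",
    alpha = "numeric",
    nBoot = "numeric",
    level = "numeric",
    bonferroniCohort = "logical",
    outputDir = "character",
    logLevel = "character"
  )
)

setValidity("RunConfig", function(object) {
  msgs <- character()
  if (!all(vapply(object@protocols, is, logical(1), "ProtocolSpec")))
    msgs <- c(msgs, "'protocols' must be a list of ProtocolSpec objects")
  if (object@nIndividuals < 1) msgs <- c(msgs, "'nIndividuals' must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1)
    msgs <- c(msgs, "'alpha' must be in (0, 1)")
  if (object@nBoot < 1) msgs <- c(msgs, "'nBoot' must be >= 1")
  if (!object@logLevel %in% c("quiet", "info"))
    msgs <- c(msgs, "'logLevel' must be 'quiet' or 'info'")
  if (length(msgs)) msgs else TRUE
})
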