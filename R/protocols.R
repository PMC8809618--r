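#' @include AllClasses.R AllGenerics.R motility.R
NULL

#' Protocol constructors
#'
#' Convenience constructors for the acquisition schemes compared by the
#' package.  `singleSnapshotProtocol(delta)` takes one image every `delta`
#' seconds and scores each timepoint as the net displacement from the
#' previous image.  `dailyVideoProtocol()` takes `boutsPerDay` bouts of
#' `boutDuration` seconds of 1-fpm imaging per day (scores = summed
#' within-bout displacement).  `hybridProtocol()` takes `imagesPerBout`
#' images spaced `intraBoutSpacing` seconds at every inter-timepoint
#' interval and scores the summed displacement across the bout.
#' `continuousProtocol()` is the gold standard itself, summed over
#' `blockDuration` blocks.
#'
#' @param delta Snapshot spacing (s).
#' @param boutsPerDay Video bouts per day (1 = daily, 2 = twice daily).
#' @param boutDuration Video bout length (s); default 15 min.
#' @param imagesPerBout Images per hybrid bout; default 7.
#' @param intraBoutSpacing Within-bout image spacing (s); default 3 min.
#' @param interTimepointInterval Bout spacing (s); default 3 h.
#' @param blockDuration Gold-standard summation block (s); default 3 h.
#' @return A validated [ProtocolSpec-class].
#' @name protocolConstructors
NULL

#' @rdname protocolConstructors
#' @export
singleSnapshotProtocol <- function(delta) {
  new("ProtocolSpec", kind = "single_snapshot",
      interTimepointInterval = delta, imagesPerBout = 1,
      intraBoutSpacing = 0, boutsPerDay = 0, boutDuration = 0)
}

#' @rdname protocolConstructors
#' @export
dailyVideoProtocol <- function(boutsPerDay = 1, boutDuration = 900) {
  new("ProtocolSpec",
      kind = if (boutsPerDay == 2) "twice_daily_video" else "daily_video",
      interTimepointInterval = 86400 / boutsPerDay, imagesPerBout = 0,
      intraBoutSpacing = 60, boutsPerDay = boutsPerDay,
      boutDuration = boutDuration)
}

#' @rdname protocolConstructors
#' @export
hybridProtocol <- function(imagesPerBout = 7, intraBoutSpacing = 180,
                           interTimepointInterval = 10800) {
  new("ProtocolSpec", kind = "hybrid_multipass",
      interTimepointInterval = interTimepointInterval,
      imagesPerBout = imagesPerBout, intraBoutSpacing = intraBoutSpacing,
      boutsPerDay = 0, boutDuration = 0)
}

#' @rdname protocolConstructors
#' @export
continuousProtocol <- function(blockDuration = 10800) {
  new("ProtocolSpec", kind = "continuous",
      interTimepointInterval = blockDuration, imagesPerBout = 0,
      intraBoutSpacing = 60, boutsPerDay = 0, boutDuration = 0)
}

# instants strictly inside an exclusion window
.instantExcluded <- function(times, ew) {
  out <- rep(FALSE, length(times))
  if (nrow(ew) > 0)
    for (k in seq_len(nrow(ew)))
      out <- out | (times > ew[k, 1] + 1e-9 & times < ew[k, 2] - 1e-9)
  out
}

# does [start, start + len] intersect any exclusion window?
.windowCollides <- function(start, len, ew) {
  if (nrow(ew) == 0) return(FALSE)
  any(start < ew[, 2] - 1e-9 & start + len > ew[, 1] + 1e-9)
}

# first bout start >= nominal (stepping by `step` s) whose [start, start+len]
# is clean and fits before slotEnd; NA when none exists
.nextCleanStart <- function(nominal, len, slotEnd, ew, step = 60) {
  s <- nominal
  while (s + len <= slotEnd + 1e-9) {
    if (!.windowCollides(s, len, ew)) return(s)
    s <- s + step
  }
  NA_real_
}

#' Score a trajectory with the Single Snapshot protocol
#'
#' One image is taken every `delta` seconds; the movement score of a
#' timepoint is the net centroid displacement from the previous image.
#' Timepoints whose image instant falls inside an exclusion window are
#' dropped.  Scores are indexed at the start of the interval they cover.
#'
#' @param traj A [Trajectory-class].
#' @param delta Inter-timepoint interval (s); must be a positive multiple
#'   of the native frame interval and shorter than the observation span.
#' @return A [ScoreSeries-class] (scores in mm).
#' @examples
#' traj <- simulateIndividual(generatorConfig(nDays = 1), 0)
#' ss <- scoreSingleSnapshot(traj, 15 * 60)
#' @export
scoreSingleSnapshot <- function(traj, delta) {
  span <- traj@t[length(traj@t)] - traj@t[1]
  if (delta > span)
    stop("'delta' is longer than the observation span")
  res <- resamplePositions(traj, delta)
  n <- length(res@t)
  if (n < 2) stop("fewer than two images at the requested interval")
  d <- sqrt(diff(res@x)^2 + diff(res@y)^2) / 1000
  tStart <- res@t[-n]
  bad <- .instantExcluded(res@t, traj@excludedWindows)
  keep <- !(bad[-n] | bad[-1])
  new("ScoreSeries", individualId = traj@individualId,
      protocol = singleSnapshotProtocol(delta),
      t = tStart[keep], score = d[keep])
}

# summed 1-fpm displacement (mm) over [start, start + len]
.boutSum <- function(fpm, start, len, requireRetained = TRUE) {
  sel <- fpm@t >= start - 1e-9 & fpm@t + fpm@interval <= start + len + 1e-9
  if (requireRetained) sel <- sel & !fpm@excluded
  sum(fpm@d[sel]) / 1000
}

#' Score a trajectory with the Daily Video protocol
#'
#' Each day is scored by `boutsPerDay` bouts of `boutDuration` seconds of
#' 1-fpm imaging, evenly spaced within the day starting at the day
#' boundary; the score is the summed minute-to-minute displacement across
#' the bout, placed at the bout's start.  A bout that would intersect an
#' exclusion window is shifted (in 1-minute steps) to the next clean window
#' of equal length within its slot; if the slot has no clean window the
#' nominal start is kept and only retained entries are summed, with a
#' warning.
#'
#' @param traj A [Trajectory-class].
#' @param boutsPerDay Bouts per day (1 = once daily, 2 = twice daily).
#' @param boutDuration Bout length (s); default 15 min.
#' @return A [ScoreSeries-class] (scores in mm).
#' @examples
#' traj <- simulateIndividual(generatorConfig(nDays = 1), 0)
#' dv <- scoreDailyVideo(traj)
#' @export
scoreDailyVideo <- function(traj, boutsPerDay = 1, boutDuration = 900) {
  spec <- dailyVideoProtocol(boutsPerDay, boutDuration)
  validObject(spec)
  fpm <- displacementSeries(traj, 60)
  span <- traj@t[length(traj@t)] - traj@t[1]
  slot <- 86400 / boutsPerDay
  nominal <- seq(0, span - boutDuration + 1e-9, by = slot)
  ts <- numeric(0)
  sc <- numeric(0)
  for (s0 in nominal) {
    s <- .nextCleanStart(s0, boutDuration, min(s0 + slot, span),
                         traj@excludedWindows)
    if (is.na(s)) {
      warning(sprintf(
        "individual %s: no clean %g-s window in the slot at %g s; summing retained entries at the nominal start",
        traj@individualId, boutDuration, s0))
      s <- s0
    }
    ts <- c(ts, s)
    sc <- c(sc, .boutSum(fpm, s, boutDuration))
  }
  new("ScoreSeries", individualId = traj@individualId, protocol = spec,
      t = ts, score = sc)
}

#' Score a trajectory with the Hybrid Multipass protocol
#'
#' At every inter-timepoint interval, `imagesPerBout` images are acquired
#' `intraBoutSpacing` seconds apart and the timepoint's score is the summed
#' displacement across the bout's consecutive image pairs.  Bouts colliding
#' with an exclusion window are shifted to the next clean start within the
#' interval; timepoints with no clean window are dropped with a warning.
#'
#' @param traj A [Trajectory-class].
#' @param imagesPerBout Images per bout (default 7).
#' @param intraBoutSpacing Spacing between images (s; default 3 min); must
#'   be a multiple of the native frame interval.
#' @param interTimepointInterval Bout spacing (s; default 3 h).
#' @return A [ScoreSeries-class] (scores in mm).
#' @examples
#' traj <- simulateIndividual(generatorConfig(nDays = 1), 0)
#' hy <- scoreHybrid(traj)
#' @export
scoreHybrid <- function(traj, imagesPerBout = 7, intraBoutSpacing = 180,
                        interTimepointInterval = 10800) {
  spec <- hybridProtocol(imagesPerBout, intraBoutSpacing,
                         interTimepointInterval)
  validObject(spec)
  native <- .nativeInterval(traj)
  if (abs(intraBoutSpacing / native - round(intraBoutSpacing / native)) >
      1e-6)
    stop("'intraBoutSpacing' must be a multiple of the native frame interval")
  boutSpan <- (imagesPerBout - 1) * intraBoutSpacing
  span <- traj@t[length(traj@t)] - traj@t[1]
  t0 <- traj@t[1]
  nominal <- seq(0, span - boutSpan + 1e-9, by = interTimepointInterval)
  ts <- numeric(0)
  sc <- numeric(0)
  for (s0 in nominal) {
    s <- .nextCleanStart(s0, boutSpan,
                         min(s0 + interTimepointInterval, span),
                         traj@excludedWindows)
    if (is.na(s)) {
      warning(sprintf(
        "individual %s: timepoint at %g s dropped (no clean bout window)",
        traj@individualId, s0))
      next
    }
    imgT <- t0 + s + (seq_len(imagesPerBout) - 1) * intraBoutSpacing
    ii <- findInterval(imgT + 1e-9, traj@t)
    xx <- traj@x[ii]
    yy <- traj@y[ii]
    ts <- c(ts, s)
    sc <- c(sc, sum(sqrt(diff(xx)^2 + diff(yy)^2)) / 1000)
  }
  new("ScoreSeries", individualId = traj@individualId, protocol = spec,
      t = ts, score = sc)
}

#' @describeIn scoreProtocol Dispatches on the spec's `kind`:
#'   `single_snapshot`, `daily_video` / `twice_daily_video`,
#'   `hybrid_multipass`, or `continuous` (gold-standard 1-fpm block
#'   totals as a ScoreSeries).
#' @export
setMethod("scoreProtocol", signature("Trajectory", "ProtocolSpec"),
  function(traj, spec, ...) {
    switch(spec@kind,
      single_snapshot = scoreSingleSnapshot(traj,
                                            spec@interTimepointInterval),
      daily_video = scoreDailyVideo(traj, spec@boutsPerDay,
                                    spec@boutDuration),
      twice_daily_video = scoreDailyVideo(traj, spec@boutsPerDay,
                                          spec@boutDuration),
      hybrid_multipass = scoreHybrid(traj, spec@imagesPerBout,
                                     spec@intraBoutSpacing,
                                     spec@interTimepointInterval),
      continuous = {
        bs <- blockTotals(displacementSeries(traj, 60),
                          spec@interTimepointInterval)
        new("ScoreSeries", individualId = traj@individualId,
            protocol = spec, t = bs@blockStart, score = bs@total)
      },
      stop("unknown protocol kind: ", spec@kind))
  })

# gold-standard comparison period for a protocol (s)
.goldPeriod <- function(spec) {
  switch(spec@kind,
    single_snapshot = spec@interTimepointInterval,
    daily_video = 86400,
    twice_daily_video = 43200,
    hybrid_multipass = spec@interTimepointInterval,
    continuous = spec@interTimepointInterval)
}

# short human-readable label for sweep tables
.protocolLabel <- function(spec) {
  switch(spec@kind,
    single_snapshot = sprintf("single_snapshot_%gmin",
                              spec@interTimepointInterval / 60),
    daily_video = "daily_video",
    twice_daily_video = "twice_daily_video",
    hybrid_multipass = sprintf("hybrid_%gx%gmin_%gh", spec@imagesPerBout,
                               spec@intraBoutSpacing / 60,
                               spec@interTimepointInterval / 3600),
    continuous = "continuous")
}

#' Sweep a cohort across acquisition protocols
#'
#' For every individual and protocol, computes the protocol's score series,
#' its fidelity to the gold standard (squared Pearson correlation between
#' protocol scores and 1-fpm totals over the protocol's matching periods,
#' via [protocolFidelity()]), the linear decline fit of the score series,
#' and the Wald-test decline classification.  Per-individual failures are
#' recorded as NA rows, not fatal errors.
#'
#' @param cohort List of [Trajectory-class] objects.
#' @param specs List of [ProtocolSpec-class] objects.
#' @param alpha Significance level for decline classification.
#' @param nComparisons Bonferroni divisor (1 = per-individual tests; set to
#'   `length(cohort)` for cohort-corrected classification).
#' @return A data.frame with one row per individual x protocol: columns
#'   `individual`, `protocol`, `fidelity_r2`, `slope`, `p_value`,
#'   `decline_detected`.
#' @examples
#' cohort <- simulateCohort(generatorConfig(nDays = 2), 3)
#' protocolSweep(cohort, list(singleSnapshotProtocol(900), hybridProtocol()))
#' @export
protocolSweep <- function(cohort, specs, alpha = 0.05, nComparisons = 1) {
  if (length(cohort) < 1) stop("'cohort' must be non-empty")
  for (sp in specs) validObject(sp)
  rows <- list()
  for (traj in cohort) {
    fpm <- displacementSeries(traj, 60)
    for (spec in specs) {
      lab <- .protocolLabel(spec)
      row <- data.frame(individual = traj@individualId, protocol = lab,
                        fidelity_r2 = NA_real_, slope = NA_real_,
                        p_value = NA_real_, decline_detected = NA)
      res <- tryCatch({
        ss <- scoreProtocol(traj, spec)
        gold <- blockTotals(fpm, .goldPeriod(spec))
        r2 <- protocolFidelity(gold, ss)
        fit <- fitDecline(ss)
        det <- classifyDecline(fit, alpha = alpha,
                               nComparisons = nComparisons)
        row$fidelity_r2 <- r2
        row$slope <- fit@slope
        row$p_value <- fit@pValue
        row$decline_detected <- det == "detected"
        row
      }, error = function(e) {
        warning(sprintf("individual %s, protocol %s: %s",
                        traj@individualId, lab, conditionMessage(e)))
        row
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
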