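#' @include AllClasses.R
NULL

# native sampling interval of a trajectory
.nativeInterval <- function(traj) {
  if (length(traj@t) < 2) stop("trajectory has fewer than 2 samples")
  min(diff(traj@t))
}

#' Restrict a trajectory to a coarser sampling interval
#'
#' Pure subsampling: retains the first sample and every sample an exact
#' multiple of `interval` after it.  No interpolation is ever performed; a
#' requested interval that is not a positive multiple of the trajectory's
#' native frame interval is an error.  Exclusion windows are carried through
#' unchanged.
#'
#' @param traj A [Trajectory-class].
#' @param interval Requested sampling interval (s).
#' @return A [Trajectory-class] on the coarser grid.
#' @examples
#' traj <- simulateIndividual(generatorConfig(nDays = 1), 0)
#' fpm <- resamplePositions(traj, 60)   # 1 frame per minute
#' @export
resamplePositions <- function(traj, interval) {
  native <- .nativeInterval(traj)
  if (length(interval) != 1L || interval <= 0)
    stop("'interval' must be a single positive duration")
  ratio <- interval / native
  if (abs(ratio - round(ratio)) > 1e-6)
    stop(sprintf(
      "interval %g s is not a multiple of the native interval %g s (no interpolation is performed)",
      interval, native))
  rel <- (traj@t - traj@t[1]) / interval
  keep <- abs(rel - round(rel)) < 1e-6
  tt <- traj@t[keep]
  ew <- traj@excludedWindows
  if (nrow(ew) > 0) {
    # windows carried through, clipped to the retained span
    ew[, 1] <- pmax(ew[, 1], tt[1])
    ew[, 2] <- pmin(ew[, 2], tt[length(tt)])
    ew <- ew[ew[, 2] > ew[, 1], , drop = FALSE]
  }
  new("Trajectory", individualId = traj@individualId,
      t = tt, x = traj@x[keep], y = traj@y[keep],
      arenaRadius = traj@arenaRadius,
      excludedWindows = ew)
}

#' Displacement magnitudes between consecutive retained samples
#'
#' Movement is measured as the change in centroid position across
#' consecutive images at the requested interval.  An entry is flagged
#' excluded (never dropped) when its spanned time intersects any exclusion
#' window, or when a gap in the underlying samples exceeds twice the
#' requested interval (missing frames in real recordings).
#'
#' @param traj A [Trajectory-class].
#' @param interval Sampling interval (s); must be a multiple of the native
#'   interval.
#' @return A [DisplacementSeries-class]; `sampleTimes()` gives interval
#'   start times, `displacements()` the magnitudes (um).
#' @examples
#' traj <- simulateIndividual(generatorConfig(nDays = 1), 0)
#' ds <- displacementSeries(traj, 60)
#' summary(displacements(ds))
#' @export
displacementSeries <- function(traj, interval = .nativeInterval(traj)) {
  res <- resamplePositions(traj, interval)
  n <- length(res@t)
  if (n < 2) stop("fewer than 2 samples at the requested interval")
  d <- sqrt(diff(res@x)^2 + diff(res@y)^2)
  tStart <- res@t[-n]
  span <- diff(res@t)
  excluded <- span > 2 * interval + 1e-9
  ew <- res@excludedWindows
  if (nrow(ew) > 0) {
    for (k in seq_len(nrow(ew)))
      excluded <- excluded |
        (tStart < ew[k, 2] - 1e-9 & tStart + span > ew[k, 1] + 1e-9)
  }
  new("DisplacementSeries", individualId = res@individualId,
      interval = interval, t = tStart, d = d, excluded = excluded)
}

#' Net displacement over a time window
#'
#' Euclidean distance between the animal's position at the last sample at
#' or before `t0` and at the last sample at or before `t1`; the path taken
#' in between is ignored.  Endpoints are acquired frames only — there is no
#' interpolation.
#'
#' @param traj A [Trajectory-class].
#' @param t0,t1 Window bounds (s), `t0 < t1`, both within the observation
#'   span.
#' @return Net displacement (um).
#' @examples
#' traj <- simulateIndividual(generatorConfig(nDays = 1), 0)
#' netDisplacement(traj, 0, 60)
#' @export
netDisplacement <- function(traj, t0, t1) {
  if (t0 >= t1) stop("'t0' must be < 't1'")
  tt <- traj@t
  if (t0 < tt[1] - 1e-9 || t1 > tt[length(tt)] + 1e-9)
    stop("window must lie within the observation span")
  i0 <- findInterval(t0 + 1e-9, tt)
  i1 <- findInterval(t1 + 1e-9, tt)
  if (i0 < 1 || i1 <= i0) stop("window contains no spanned samples")
  sqrt((traj@x[i1] - traj@x[i0])^2 + (traj@y[i1] - traj@y[i0])^2)
}

#' Sum displacements over fixed blocks
#'
#' Sums the non-excluded displacement entries within consecutive blocks
#' anchored at the onset of adulthood (t = 0), converting to mm.  Block
#' sums are raw sums of retained entries with no rescaling for excluded
#' time; `nContributing()` exposes the retained entry count per block so
#' users can rescale.
#'
#' @param ds A [DisplacementSeries-class].
#' @param blockDuration Block length (s); default 3 h.
#' @return A [BlockSeries-class].
#' @examples
#' traj <- simulateIndividual(generatorConfig(nDays = 1), 0)
#' bs <- blockTotals(displacementSeries(traj, 60))
#' totals(bs)
#' @export
blockTotals <- function(ds, blockDuration = 10800) {
  if (length(ds@d) < 1) stop("displacement series is empty")
  if (blockDuration < ds@interval)
    stop("'blockDuration' must be >= the sampling interval")
  idx <- floor(ds@t / blockDuration + 1e-9)
  maxIdx <- max(idx)
  minIdx <- min(0, min(idx))
  blocks <- minIdx:maxIdx
  keep <- !ds@excluded
  fac <- factor(idx, levels = blocks)
  total <- as.numeric(tapply(ifelse(keep, ds@d, 0), fac, sum,
                             default = 0)) / 1000
  ncontrib <- as.integer(tapply(keep, fac, sum, default = 0))
  new("BlockSeries", individualId = ds@individualId,
      blockDuration = blockDuration, blockStart = blocks * blockDuration,
      total = total, nContributing = ncontrib)
}

#' Per-day movement totals
#'
#' Calendar-day sums (24-h windows anchored at the onset of adulthood) of
#' non-excluded displacement, in mm.  Days are numbered from 1, so day 1 is
#' the first 24 h of adulthood.
#'
#' @param ds A [DisplacementSeries-class] spanning at least one day.
#' @return A data.frame with columns `day`, `total_mm`, `n_contributing`.
#' @examples
#' traj <- simulateIndividual(generatorConfig(nDays = 1), 0)
#' dailyTotals(displacementSeries(traj, 60))
#' @export
dailyTotals <- function(ds) {
  if (max(ds@t) - min(ds@t) < 86400 - ds@interval - 1e-9)
    stop("observation must span at least one day")
  bs <- blockTotals(ds, 86400)
  data.frame(day = as.integer(bs@blockStart / 86400) + 1L,
             total_mm = bs@total,
             n_contributing = bs@nContributing)
}
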