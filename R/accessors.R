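#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("individualId", "Trajectory", function(object) object@individualId)
#' @rdname accessors
setMethod("individualId", "DisplacementSeries",
          function(object) object@individualId)
#' @rdname accessors
setMethod("individualId", "BlockSeries", function(object) object@individualId)
#' @rdname accessors
setMethod("individualId", "ScoreSeries", function(object) object@individualId)

#' @rdname accessors
setMethod("arenaRadius", "Trajectory", function(object) object@arenaRadius)
#' @rdname accessors
setMethod("arenaRadius", "GeneratorConfig", function(object) object@arenaRadius)

#' @rdname accessors
setMethod("excludedWindows", "Trajectory",
          function(object) object@excludedWindows)

#' @rdname accessors
setMethod("sampleTimes", "Trajectory", function(object) object@t)
#' @rdname accessors
setMethod("sampleTimes", "DisplacementSeries", function(object) object@t)
#' @rdname accessors
setMethod("sampleTimes", "ScoreSeries", function(object) object@t)

#' @rdname accessors
setMethod("positions", "Trajectory",
          function(object) cbind(x = object@x, y = object@y))

#' @rdname accessors
setMethod("displacements", "DisplacementSeries", function(object) object@d)
#' @rdname accessors
setMethod("excludedMask", "DisplacementSeries",
          function(object) object@excluded)
#' @rdname accessors
setMethod("samplingInterval", "DisplacementSeries",
          function(object) object@interval)

#' @rdname accessors
setMethod("blockStarts", "BlockSeries", function(object) object@blockStart)
#' @rdname accessors
setMethod("blockDuration", "BlockSeries",
          function(object) object@blockDuration)
#' @rdname accessors
setMethod("totals", "BlockSeries", function(object) object@total)
#' @rdname accessors
setMethod("nContributing", "BlockSeries",
          function(object) object@nContributing)

#' @rdname accessors
setMethod("scores", "ScoreSeries", function(object) object@score)
#' @rdname accessors
setMethod("protocolKind", "ScoreSeries",
          function(object) object@protocol@kind)
#' @rdname accessors
setMethod("protocolKind", "ProtocolSpec", function(object) object@kind)

#' @rdname accessors
setMethod("declineSlope", "DeclineFit", function(object) object@slope)
#' @rdname accessors
setMethod("pValue", "DeclineFit", function(object) object@pValue)
#' @rdname accessors
setMethod("rSquared", "DeclineFit", function(object) object@rSquared)

#' @rdname accessors
setMethod("confInt", "BootstrapCI",
          function(object) c(lower = object@lower, upper = object@upper))

#' @rdname accessors
setMethod("lawnArea", "LawnMask", function(object) object@area)
#' @rdname accessors
setMethod("maskPixels", "LawnMask", function(object) object@mask)
#' @rdname accessors
setMethod("imagePixels", "ArenaImage", function(object) object@pixels)
#' @rdname accessors
setMethod("pixelSize", "ArenaImage", function(object) object@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "LawnMask", function(object) object@pixelSize)

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig:",
      sprintf("arena %g um, %g days at %g s/frame", object@arenaRadius,
              object@nDays, object@frameInterval), "\n")
  cat(sprintf("  day-0 block total %g mm, decline %g mm/block/day (SD %g)\n",
              object@meanDay0BlockTotal, object@populationDeclineRate,
              object@individualRateSd))
  cat(sprintf("  level SD %g, day volatility %g, seed %d\n",
              object@individualLevelSd, object@dayLevelVolatility,
              object@seed))
})

setMethod("show", "Trajectory", function(object) {
  n <- length(object@t)
  cat(sprintf(
    "Trajectory '%s': %d samples over %.2f days, arena radius %g um, %d exclusion window(s)\n",
    object@individualId, n,
    if (n) (object@t[n] - object@t[1]) / 86400 else 0,
    object@arenaRadius, nrow(object@excludedWindows)))
})

setMethod("show", "DisplacementSeries", function(object) {
  cat(sprintf(
    "DisplacementSeries '%s': %d entries at %g s interval (%d excluded)\n",
    object@individualId, length(object@d), object@interval,
    sum(object@excluded)))
})

setMethod("show", "BlockSeries", function(object) {
  cat(sprintf(
    "BlockSeries '%s': %d blocks of %g h; total %.1f mm\n",
    object@individualId, length(object@total), object@blockDuration / 3600,
    sum(object@total)))
})

setMethod("show", "ProtocolSpec", function(object) {
  cat("ProtocolSpec:", object@kind, "\n")
  k <- object@kind
  if (k == "single_snapshot")
    cat(sprintf("  one image every %g min\n",
                object@interTimepointInterval / 60))
  if (k %in% c("daily_video", "twice_daily_video"))
    cat(sprintf("  %g bout(s)/day of %g min\n", object@boutsPerDay,
                object@boutDuration / 60))
  if (k == "hybrid_multipass")
    cat(sprintf("  %g images spaced %g min, every %g h\n",
                object@imagesPerBout, object@intraBoutSpacing / 60,
                object@interTimepointInterval / 3600))
})

setMethod("show", "ScoreSeries", function(object) {
  cat(sprintf("ScoreSeries '%s' (%s): %d timepoints\n",
              object@individualId, object@protocol@kind, length(object@score)))
})

setMethod("show", "DeclineFit", function(object) {
  cat(sprintf(
    "DeclineFit: slope %.4g /day, intercept %.4g, R^2 %.3f, p %.3g (n = %d)%s\n",
    object@slope, object@intercept, object@rSquared, object@pValue,
    object@nPoints, if (object@degenerate) " [degenerate]" else ""))
  cat(sprintf("  biological interest (p<0.05 & R^2>0.10): %s\n",
              biologicalInterest(object)))
})

setMethod("show", "BootstrapCI", function(object) {
  cat(sprintf("BootstrapCI: %.4g [%.4g, %.4g] (%g%%, %d replicates)\n",
              object@pointEstimate, object@lower, object@upper,
              100 * object@level, object@nBoot))
})

setMethod("show", "ArenaImage", function(object) {
  cat(sprintf(
    "ArenaImage: %d x %d px at %g um/px; lawn r = %g um, noise SD %g\n",
    nrow(object@pixels), ncol(object@pixels), object@pixelSize,
    object@lawnRadius, object@noiseSd))
})

setMethod("show", "LawnMask", function(object) {
  cat(sprintf("LawnMask: %.4g mm^2 from %d frame(s) at %g um/px\n",
              object@area, object@nFramesCombined, object@pixelSize))
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf(
    "RunConfig: %g individuals, %d protocol(s), alpha %g, %g bootstrap reps\n",
    object@nIndividuals, length(object@protocols), object@alpha,
    object@nBoot))
})
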