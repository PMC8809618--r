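#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor family used across the package's classes instead of
#' direct slot access.
#'
#' @param object An object of one of the package's classes.
#' @return The slot value named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("individualId", function(object) standardGeneric("individualId"))

#' @rdname accessors
#' @export
setGeneric("arenaRadius", function(object) standardGeneric("arenaRadius"))

#' @rdname accessors
#' @export
setGeneric("excludedWindows",
           function(object) standardGeneric("excludedWindows"))

#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))

#' @rdname accessors
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))

#' @rdname accessors
#' @export
setGeneric("displacements", function(object) standardGeneric("displacements"))

#' @rdname accessors
#' @export
setGeneric("excludedMask", function(object) standardGeneric("excludedMask"))

#' @rdname accessors
#' @export
setGeneric("samplingInterval",
           function(object) standardGeneric("samplingInterval"))

#' @rdname accessors
#' @export
setGeneric("blockStarts", function(object) standardGeneric("blockStarts"))

#' @rdname accessors
#' @export
setGeneric("blockDuration", function(object) standardGeneric("blockDuration"))

#' @rdname accessors
#' @export
setGeneric("totals", function(object) standardGeneric("totals"))

#' @rdname accessors
#' @export
setGeneric("nContributing", function(object) standardGeneric("nContributing"))

#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("protocolKind", function(object) standardGeneric("protocolKind"))

#' @rdname accessors
#' @export
setGeneric("declineSlope", function(object) standardGeneric("declineSlope"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' @rdname accessors
#' @export
setGeneric("confInt", function(object) standardGeneric("confInt"))

#' @rdname accessors
#' @export
setGeneric("lawnArea", function(object) standardGeneric("lawnArea"))

#' @rdname accessors
#' @export
setGeneric("maskPixels", function(object) standardGeneric("maskPixels"))

#' @rdname accessors
#' @export
setGeneric("imagePixels", function(object) standardGeneric("imagePixels"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' Fit a linear movement-decline model
#'
#' @param object A [BlockSeries-class], [ScoreSeries-class], or numeric
#'   vector of times in days (with `values`).
#' @param ... Passed to methods.
#' @export
setGeneric("fitDecline", function(object, ...) standardGeneric("fitDecline"))

#' Score a trajectory under an acquisition protocol
#'
#' @param traj A [Trajectory-class].
#' @param spec A [ProtocolSpec-class].
#' @param ... Passed to the kind-specific scorer.
#' @export
setGeneric("scoreProtocol",
           function(traj, spec, ...) standardGeneric("scoreProtocol"))
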