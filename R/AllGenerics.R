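# Accessor generics (slot access stays internal to the package).

#' @title Accessors for speckletrack objects
#' @description \code{intensity} returns the intensity grid of a
#'   [SpeckleFrame-class] or [ObjectScene-class]; \code{pitch} the sampling
#'   pitch (mm/px); \code{frames} the frame list of a [SceneSequence-class];
#'   \code{values} the lag grid of a [CorrelationMap-class];
#'   \code{trajectoryTable} the per-step table of a [Trajectory-class].
#' @param x The object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("pitch", function(x) standardGeneric("pitch"))

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname accessors
#' @export
setGeneric("trajectoryTable", function(x) standardGeneric("trajectoryTable"))

#' @rdname accessors
#' @export
setMethod("intensity", "SpeckleFrame", function(x) x@intensity)

#' @rdname accessors
#' @export
setMethod("intensity", "ObjectScene", function(x) x@intensity)

#' @rdname accessors
#' @export
setMethod("pitch", "SpeckleFrame", function(x) x@pitch)

#' @rdname accessors
#' @export
setMethod("pitch", "ObjectScene", function(x) x@pitch)

#' @rdname accessors
#' @export
setMethod("pitch", "CorrelationMap", function(x) x@pitch)

#' @rdname accessors
#' @export
setMethod("frames", "SceneSequence", function(x) x@frames)

#' @rdname accessors
#' @export
setMethod("values", "CorrelationMap", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("trajectoryTable", "Trajectory", function(x) x@table)
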