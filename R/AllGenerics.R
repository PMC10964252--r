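#' @name CardioPIV-accessors
#' @title Accessor generics for CardioPIV classes
#' @description Getter generics for the package's S4 containers. Use these
#'   rather than reaching into slots with `@`.
#' @param x an object of the documented class.
#' @keywords internal
NULL

#' @rdname CardioPIV-accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname CardioPIV-accessors
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))

#' @rdname CardioPIV-accessors
#' @export
setGeneric("pixelScale", function(x) standardGeneric("pixelScale"))

#' @rdname CardioPIV-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname CardioPIV-accessors
#' @export
setGeneric("frameDim", function(x) standardGeneric("frameDim"))

#' @rdname CardioPIV-accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname CardioPIV-accessors
#' @export
setGeneric("displacements", function(x) standardGeneric("displacements"))

#' @rdname CardioPIV-accessors
#' @export
setGeneric("traceTime", function(x) standardGeneric("traceTime"))

#' @rdname CardioPIV-accessors
#' @export
setGeneric("rawSpeed", function(x) standardGeneric("rawSpeed"))

#' @rdname CardioPIV-accessors
#' @export
setGeneric("smoothSpeed", function(x) standardGeneric("smoothSpeed"))

#' @rdname CardioPIV-accessors
#' @export
setGeneric("beats", function(x) standardGeneric("beats"))

#' @rdname CardioPIV-accessors
#' @export
setGeneric("nBeats", function(x) standardGeneric("nBeats"))

#' @rdname CardioPIV-accessors
#' @export
setGeneric("perBeat", function(x) standardGeneric("perBeat"))

#' @rdname CardioPIV-accessors
#' @export
setGeneric("aggregated", function(x) standardGeneric("aggregated"))

#' @rdname CardioPIV-accessors
#' @export
setGeneric("parameterUnits", function(x) standardGeneric("parameterUnits"))
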