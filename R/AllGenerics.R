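#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param object an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("clipDuration", function(object) standardGeneric("clipDuration"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("site", function(object) standardGeneric("site"))

#' @rdname accessors
#' @export
setGeneric("clipLabel", function(object) standardGeneric("clipLabel"))

#' @rdname accessors
#' @export
setGeneric("systolicIntervals",
           function(object) standardGeneric("systolicIntervals"))

#' @rdname accessors
#' @export
setGeneric("specFrames", function(object) standardGeneric("specFrames"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setGeneric("eplValues", function(object) standardGeneric("eplValues"))

#' @rdname accessors
#' @export
setGeneric("eplMask", function(object) standardGeneric("eplMask"))
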