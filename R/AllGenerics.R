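#' @rdname dosages
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname dosages
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname dosages
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname covOps
#' @export
setGeneric("covIds", function(x) standardGeneric("covIds"))

#' @rdname covOps
#' @export
setGeneric("covDim", function(x) standardGeneric("covDim"))

#' @rdname covOps
#' @export
setGeneric("covMatrix", function(x) standardGeneric("covMatrix"))

#' @rdname covOps
#' @export
setGeneric("covInverse", function(x) standardGeneric("covInverse"))

#' @rdname covOps
#' @export
setGeneric("covLogDet", function(x) standardGeneric("covLogDet"))

#' @rdname remlFit
#' @export
setGeneric("varComp", function(fit) standardGeneric("varComp"))

#' @rdname remlFit
#' @export
setGeneric("fixedEffects", function(fit) standardGeneric("fixedEffects"))
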