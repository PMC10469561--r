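#' @import methods
NULL

#' Accessor generics
#'
#' Slot accessors for the core raster and curve classes. Bioconductor-style
#' accessors are the supported interface; slots are internal.
#'
#' @param object An object of one of the faquant S4 classes.
#' @return The corresponding slot value.
#' @name faquant-accessors
#' @rdname faquant-accessors
NULL

#' @rdname faquant-accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname faquant-accessors
#' @export
setGeneric("bitDepth", function(object) standardGeneric("bitDepth"))

#' @rdname faquant-accessors
#' @export
setGeneric("pixelSizeUm", function(object) standardGeneric("pixelSizeUm"))

#' @rdname faquant-accessors
#' @export
setGeneric("maskArea", function(object) standardGeneric("maskArea"))

#' @rdname faquant-accessors
#' @export
setGeneric("maskCentroid", function(object) standardGeneric("maskCentroid"))

#' @rdname faquant-accessors
#' @export
setGeneric("distanceMap", function(object) standardGeneric("distanceMap"))

#' @rdname faquant-accessors
#' @export
setGeneric("maxBorderDist", function(object) standardGeneric("maxBorderDist"))

#' @rdname faquant-accessors
#' @export
setGeneric("labelMatrix", function(object) standardGeneric("labelMatrix"))

#' @rdname faquant-accessors
#' @export
setGeneric("nLabels", function(object) standardGeneric("nLabels"))

#' @rdname faquant-accessors
#' @export
setGeneric("frapTimes", function(object) standardGeneric("frapTimes"))

#' @rdname faquant-accessors
#' @export
setGeneric("frapIntensities", function(object) standardGeneric("frapIntensities"))

#' @rdname faquant-accessors
#' @export
setGeneric("frapRole", function(object) standardGeneric("frapRole"))

#' @rdname faquant-accessors
#' @export
setGeneric("nPreBleach", function(object) standardGeneric("nPreBleach"))

#' @rdname faquant-accessors
#' @export
setGeneric("recoveryRate", function(object) standardGeneric("recoveryRate"))

#' @rdname faquant-accessors
#' @export
setGeneric("halfTime", function(object) standardGeneric("halfTime"))

#' @rdname faquant-accessors
#' @export
setGeneric("mobileFraction", function(object) standardGeneric("mobileFraction"))
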