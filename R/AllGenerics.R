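## Generics for the accessor layer.

#' @rdname Spectrum-accessors
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("spectrumRole", function(object) standardGeneric("spectrumRole"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("spectrumMeta", function(object) standardGeneric("spectrumMeta"))

#' @rdname affected-accessors
#' @export
setGeneric("affectedSpectrum",
           function(object) standardGeneric("affectedSpectrum"))

#' @rdname affected-accessors
#' @export
setGeneric("affectedNumber",
           function(object) standardGeneric("affectedNumber"))

#' @rdname ternary-accessors
#' @export
setGeneric("theoreticalSpectrum",
           function(object) standardGeneric("theoreticalSpectrum"))

#' @rdname ternary-accessors
#' @export
setGeneric("sharedSpectrum", function(object) standardGeneric("sharedSpectrum"))

#' @rdname ternary-accessors
#' @export
setGeneric("sharedCount", function(object) standardGeneric("sharedCount"))

#' @rdname ternary-accessors
#' @export
setGeneric("retainedWeights",
           function(object) standardGeneric("retainedWeights"))

#' @rdname ternary-accessors
#' @export
setGeneric("sharePercent", function(object) standardGeneric("sharePercent"))

#' @rdname ternary-accessors
#' @export
setGeneric("deltaN", function(object) standardGeneric("deltaN"))

#' @rdname ternary-accessors
#' @export
setGeneric("interactionLabel",
           function(object) standardGeneric("interactionLabel"))

#' @rdname distance-accessors
#' @export
setGeneric("distanceGrid", function(object) standardGeneric("distanceGrid"))

#' @rdname distance-accessors
#' @export
setGeneric("distanceDensity",
           function(object) standardGeneric("distanceDensity"))

#' @rdname distance-accessors
#' @export
setGeneric("distanceMode", function(object) standardGeneric("distanceMode"))

#' @rdname distance-accessors
#' @export
setGeneric("distanceMean", function(object) standardGeneric("distanceMean"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("nAtoms", function(object) standardGeneric("nAtoms"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("frameCoords",
           function(object, i) standardGeneric("frameCoords"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("boxLengths", function(object, i) standardGeneric("boxLengths"))
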