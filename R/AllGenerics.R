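#' @rdname SpectraSet
#' @param x,object a `SpectraSet` (or the object documented).
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname SpectraSet
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname SpectraSet
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname SpectraSet
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname detectPeaks
#' @export
setGeneric("detectPeaks", function(curve, minPromFrac = 0.05,
                                   smoothWindow = 5L)
  standardGeneric("detectPeaks"))

#' @rdname crushingStrength
#' @export
setGeneric("crushingStrength", function(curve, ...)
  standardGeneric("crushingStrength"))

#' @rdname ghValues
#' @export
setGeneric("ghValues", function(model, x, threshold = 3.0)
  standardGeneric("ghValues"))
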