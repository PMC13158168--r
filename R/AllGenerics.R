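#' @rdname EnergyGrid-class
#' @param object,x an object
#' @export
setGeneric("gridEdges", function(x) standardGeneric("gridEdges"))

#' @rdname EnergyGrid-class
#' @export
setGeneric("gridMidpoints", function(x) standardGeneric("gridMidpoints"))

#' @rdname EnergyGrid-class
#' @export
setGeneric("nGroups", function(x) standardGeneric("nGroups"))

#' @rdname EnergyGrid-class
#' @export
setGeneric("groupRegions", function(x) standardGeneric("groupRegions"))

#' @rdname NeutronSpectrum-class
#' @param x an object
#' @export
setGeneric("fluence", function(x) standardGeneric("fluence"))

#' @rdname NeutronSpectrum-class
#' @export
setGeneric("totalFluence", function(x) standardGeneric("totalFluence"))

#' @rdname ReferenceLocation-class
#' @param x an object
#' @export
setGeneric("responseMatrix", function(x) standardGeneric("responseMatrix"))

#' @rdname ReferenceLocation-class
#' @export
setGeneric("doseComponents", function(x) standardGeneric("doseComponents"))

#' @rdname ReferenceLocation-class
#' @export
setGeneric("hStarReference", function(x) standardGeneric("hStarReference"))

#' @rdname ReferenceLocation-class
#' @export
setGeneric("gammaReference", function(x) standardGeneric("gammaReference"))

#' @rdname ReferenceLocation-class
#' @export
setGeneric("primaryFraction", function(x) standardGeneric("primaryFraction"))

#' @rdname ReferenceLibrary-class
#' @param x an object
#' @export
setGeneric("locationIds", function(x) standardGeneric("locationIds"))

#' @rdname ReferenceLibrary-class
#' @param id location identifier
#' @export
setGeneric("refLocation", function(x, id) standardGeneric("refLocation"))

#' @rdname ReferenceLibrary-class
#' @export
setGeneric("distanceCm", function(x) standardGeneric("distanceCm"))

#' @rdname NormalizationFactors-class
#' @param x an object
#' @export
setGeneric("normFactors", function(x) standardGeneric("normFactors"))

#' @rdname NormalizationFactors-class
#' @export
setGeneric("conditionNumber", function(x) standardGeneric("conditionNumber"))
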