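#' @rdname EnergyGrid-class
#' @export
setMethod("gridEdges", "EnergyGrid", function(x) x@edges)

#' @rdname EnergyGrid-class
#' @export
setMethod("gridMidpoints", "EnergyGrid", function(x) {
  sqrt(x@edges[-length(x@edges)] * x@edges[-1])
})

#' @rdname EnergyGrid-class
#' @export
setMethod("nGroups", "EnergyGrid", function(x) length(x@edges) - 1L)

#' @rdname EnergyGrid-class
#' @export
setMethod("groupRegions", "EnergyGrid", function(x) x@regionOfGroup)

#' @rdname NeutronSpectrum-class
#' @export
setMethod("fluence", "NeutronSpectrum", function(x) x@fluence)

#' @rdname NeutronSpectrum-class
#' @export
setMethod("totalFluence", "NeutronSpectrum", function(x) sum(x@fluence))

#' @rdname ReferenceLocation-class
#' @export
setMethod("responseMatrix", "ReferenceLocation", function(x) x@Rsim)

#' @rdname ReferenceLocation-class
#' @export
setMethod("doseComponents", "ReferenceLocation", function(x) x@Dref)

#' @rdname ReferenceLocation-class
#' @export
setMethod("hStarReference", "ReferenceLocation", function(x) x@Href)

#' @rdname ReferenceLocation-class
#' @export
setMethod("gammaReference", "ReferenceLocation", function(x) x@gammaGy)

#' @rdname ReferenceLocation-class
#' @export
setMethod("primaryFraction", "ReferenceLocation", function(x) x@gammaPrimaryFraction)

#' @rdname ReferenceLibrary-class
#' @export
setMethod("locationIds", "ReferenceLibrary", function(x) {
  vapply(x@locations, function(l) l@locationId, character(1))
})

#' @rdname ReferenceLibrary-class
#' @export
setMethod("refLocation", "ReferenceLibrary", function(x, id) {
  ids <- locationIds(x)
  if (!id %in% ids) stop("unknown location id: ", id)
  x@locations[[match(id, ids)]]
})

#' @rdname ReferenceLibrary-class
#' @export
setMethod("distanceCm", "ReferenceLibrary", function(x) {
  stats::setNames(vapply(x@locations, function(l) l@distanceCm, numeric(1)),
                  locationIds(x))
})

#' @rdname NormalizationFactors-class
#' @export
setMethod("normFactors", "NormalizationFactors", function(x) x@N)

#' @rdname NormalizationFactors-class
#' @export
setMethod("conditionNumber", "NormalizationFactors", function(x) x@conditionNumber)

setMethod("show", "EnergyGrid", function(object) {
  tab <- table(object@regionOfGroup)[REGIONS]
  cat("EnergyGrid:", nGroups(object), "groups,",
      format(object@edges[1]), "-", format(object@edges[length(object@edges)]),
      "MeV\n  groups per region:",
      paste(REGIONS, as.integer(tab), sep = "=", collapse = ", "), "\n")
})

setMethod("show", "NeutronSpectrum", function(object) {
  cat("NeutronSpectrum at '", object@locationId, "': total fluence ",
      format(totalFluence(object), digits = 4), " n/cm2/C over ",
      nGroups(object@grid), " groups\n", sep = "")
})

setMethod("show", "ReferenceLocation", function(object) {
  cat("ReferenceLocation '", object@locationId, "' (",
      object@distanceCm, " cm from field center)\n", sep = "")
  cat("  gamma ", format(object@gammaGy, digits = 3), " Gy (primary fraction ",
      format(object@gammaPrimaryFraction, digits = 3), "), H* ",
      format(sum(object@Href), digits = 3), " Sv\n", sep = "")
})

setMethod("show", "ReferenceLibrary", function(object) {
  cat("ReferenceLibrary with", length(object@locations), "locations:",
      paste(locationIds(object), collapse = ", "), "\n")
})

setMethod("show", "NormalizationFactors", function(object) {
  cat("NormalizationFactors '", object@locationId, "': ", sep = "")
  cat(paste(names(object@N), format(object@N, digits = 4), sep = "=",
            collapse = ", "),
      sprintf(" (cond %.3g%s%s)\n", object@conditionNumber,
              if (object@flagNegative) ", NEGATIVE" else "",
              if (object@flagIllConditioned) ", ILL-CONDITIONED" else ""))
})

setMethod("show", "DoseExperiment", function(object) {
  cat("DoseExperiment:", nrow(object), "locations x", ncol(object),
      "patients;", length(SummarizedExperiment::assayNames(object)),
      "dose assays\n")
  callNextMethod()
})
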