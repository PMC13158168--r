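#' @import methods
NULL

#' Multigroup neutron energy grid
#'
#' Fine energy-group structure used for spectrum folding, with the three
#' macroscopic energy regions of BNCT dosimetry: thermal
#' (up to 5.3e-7 MeV), epithermal (up to 1e-2 MeV) and fast (up to 30 MeV).
#' Group membership is decided by the geometric-mean midpoint of each group;
#' region intervals are upper-inclusive, matching the conventional
#' "Elow < En <= Ehigh" notation.
#'
#' @slot edges strictly increasing group edges in MeV, spanning at least
#'   1e-20 to 30 MeV
#' @slot regionBounds the two region cut energies in MeV,
#'   c(5.3e-7, 1e-2); both must coincide with grid edges
#' @slot regionOfGroup region label ("thermal", "epithermal", "fast")
#'   of each fine group
#' @seealso [energyGrid()], [defaultEnergyGrid()], [regionOfEnergy()]
#' @export
setClass("EnergyGrid",
  representation(edges = "numeric", regionBounds = "numeric",
                 regionOfGroup = "character"))

setValidity("EnergyGrid", function(object) {
  msg <- character()
  e <- object@edges
  if (length(e) < 4L || is.unsorted(e, strictly = TRUE))
    msg <- c(msg, "edges must be strictly increasing with >= 4 values")
  if (e[1] > 1e-20) msg <- c(msg, "first edge must be <= 1e-20 MeV")
  if (e[length(e)] < 30) msg <- c(msg, "last edge must be >= 30 MeV")
  if (!identical(object@regionBounds, c(5.3e-7, 1e-2)))
    msg <- c(msg, "region cuts must equal 5.3e-7 and 1e-2 MeV exactly")
  if (!all(object@regionBounds %in% e))
    msg <- c(msg, "region cut energies must coincide with grid edges")
  if (length(object@regionOfGroup) != length(e) - 1L)
    msg <- c(msg, "regionOfGroup must have one label per group")
  if (!all(object@regionOfGroup %in% REGIONS))
    msg <- c(msg, "region labels must be thermal/epithermal/fast")
  if (!all(REGIONS %in% object@regionOfGroup))
    msg <- c(msg, "every region must contain at least one group")
  if (length(msg)) msg else TRUE
})

#' Multigroup neutron spectrum at one body location
#'
#' Group fluence per unit delivered beam charge (n/cm2/C) on an
#' [EnergyGrid-class].
#'
#' @slot locationId body location identifier
#' @slot grid the [EnergyGrid-class] the fluence is defined on
#' @slot fluence nonnegative group fluence, n/cm2/C, one value per group
#' @seealso [buildSpectrum()], [foldReactionRate()], [foldHStar()]
#' @export
setClass("NeutronSpectrum",
  representation(locationId = "character", grid = "EnergyGrid",
                 fluence = "numeric"))

setValidity("NeutronSpectrum", function(object) {
  msg <- character()
  if (length(object@fluence) != length(object@grid@edges) - 1L)
    msg <- c(msg, "fluence must have one value per grid group")
  if (any(!is.finite(object@fluence)) || any(object@fluence < 0))
    msg <- c(msg, "fluence must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' Group-averaged reaction cross sections for one foil
#'
#' Lethargy-weighted group-average cross sections (barns) on an
#' [EnergyGrid-class], produced by [groupAverageSigma()].
#'
#' @slot foil foil name ("Au", "Mn" or "Al")
#' @slot sigma group-average cross section in barns, one value per group
#' @export
setClass("CrossSectionTable",
  representation(foil = "character", sigma = "numeric"))

setValidity("CrossSectionTable", function(object) {
  if (any(!is.finite(object@sigma)) || any(object@sigma < 0))
    "sigma must be finite and >= 0" else TRUE
})

#' Reference dosimetric record for one body location
#'
#' Per-location reference quantities against which patient measurements are
#' unfolded: the 3x3 foil-by-region reaction-rate response matrix, per-region
#' physical dose components at the 25 ppm reference blood-boron
#' concentration, per-region ambient dose equivalent H*(10), and the gamma
#' dose with its primary (beam-line) fraction.
#'
#' @slot locationId body location identifier
#' @slot distanceCm lateral distance from the irradiation field center, cm
#' @slot distanceEdgeCm distance from the field edge, cm
#' @slot Rsim 3x3 response matrix, rows = foils (Au, Mn, Al), columns =
#'   regions (thermal, epithermal, fast), n/C/atom
#' @slot Dref 3x3 physical dose components per treatment, rows = components
#'   (boron, nitrogen, hydrogen), columns = regions, Gy (boron at 25 ppm)
#' @slot Href per-region H*(10) per treatment, Sv
#' @slot gammaGy total gamma absorbed dose per treatment, Gy
#' @slot gammaPrimaryFraction fraction of the gamma dose originating from the
#'   beam line / room (primary), in [0, 1]
#' @seealso [buildReferenceRecord()], [buildReferenceLibrary()]
#' @export
setClass("ReferenceLocation",
  representation(locationId = "character", distanceCm = "numeric",
                 distanceEdgeCm = "numeric", Rsim = "matrix", Dref = "matrix",
                 Href = "numeric", gammaGy = "numeric",
                 gammaPrimaryFraction = "numeric"))

setValidity("ReferenceLocation", function(object) {
  msg <- character()
  R <- object@Rsim
  if (!all(dim(R) == c(3L, 3L)) ||
      !identical(rownames(R), FOILS) || !identical(colnames(R), REGIONS))
    msg <- c(msg, "Rsim must be 3x3 with rows Au/Mn/Al and columns thermal/epithermal/fast")
  else {
    if (any(R < 0)) msg <- c(msg, "Rsim entries must be >= 0")
    if (R["Al", "thermal"] > min(R[c("Au", "Mn"), "thermal"]))
      msg <- c(msg, "thermal column must be dominated by the Au and Mn rows")
    if (R["Mn", "fast"] > min(R["Mn", ]))
      msg <- c(msg, "fast entry of the Mn row must be the smallest of its row")
  }
  D <- object@Dref
  if (!all(dim(D) == c(3L, 3L)) ||
      !identical(rownames(D), c("boron", "nitrogen", "hydrogen")) ||
      !identical(colnames(D), REGIONS))
    msg <- c(msg, "Dref must be 3x3 with rows boron/nitrogen/hydrogen and region columns")
  else if (any(D < 0)) msg <- c(msg, "dose components must be >= 0")
  if (length(object@Href) != 3L || any(object@Href < 0))
    msg <- c(msg, "Href must be three nonnegative per-region values")
  if (object@gammaGy < 0) msg <- c(msg, "gamma dose must be >= 0")
  if (object@gammaPrimaryFraction < 0 || object@gammaPrimaryFraction > 1)
    msg <- c(msg, "gamma primary fraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Reference library: all body locations plus folding provenance
#'
#' @slot locations list of [ReferenceLocation-class] objects in field-to-foot
#'   order (neck through ankle by default)
#' @slot gridEdges edges of the energy grid the library was folded on (MeV)
#' @slot chargeC delivered beam charge per treatment used for per-treatment
#'   scaling, C
#' @slot fieldEdgeOffsetCm distance between field center and field edge, cm
#' @slot schemaVersion integer schema version of the serialized form
#' @seealso [buildReferenceLibrary()], [readReferenceLibrary()]
#' @export
setClass("ReferenceLibrary",
  representation(locations = "list", gridEdges = "numeric",
                 chargeC = "numeric", fieldEdgeOffsetCm = "numeric",
                 schemaVersion = "integer"))

setValidity("ReferenceLibrary", function(object) {
  msg <- character()
  if (!length(object@locations) ||
      !all(vapply(object@locations, is, logical(1), "ReferenceLocation")))
    msg <- c(msg, "locations must be a non-empty list of ReferenceLocation")
  else {
    ids <- vapply(object@locations, function(l) l@locationId, character(1))
    if (anyDuplicated(ids)) msg <- c(msg, "location ids must be unique")
  }
  if (object@chargeC <= 0) msg <- c(msg, "chargeC must be > 0")
  if (length(msg)) msg else TRUE
})

#' Unfolded per-region normalization factors for one measurement point
#'
#' The three measured-to-reference response ratios (thermal, epithermal,
#' fast) obtained from the 3x3 linear solve, with conditioning diagnostics.
#' Negative components are preserved (never silently truncated) and flagged.
#'
#' @slot locationId body location identifier
#' @slot N named 3-vector of normalization factors (thermal, epithermal,
#'   fast), dimensionless
#' @slot nSd first-order propagated standard deviations of N (NA when no
#'   measurement uncertainties were supplied)
#' @slot conditionNumber condition number of the response matrix
#' @slot flagNegative TRUE if any unfolded component was negative
#' @slot flagIllConditioned TRUE if the condition number exceeded the
#'   configured threshold
#' @seealso [solveNormalization()]
#' @export
setClass("NormalizationFactors",
  representation(locationId = "character", N = "numeric", nSd = "numeric",
                 conditionNumber = "numeric", flagNegative = "logical",
                 flagIllConditioned = "logical"))

setValidity("NormalizationFactors", function(object) {
  msg <- character()
  if (length(object@N) != 3L || !identical(names(object@N), REGIONS))
    msg <- c(msg, "N must be a named 3-vector over thermal/epithermal/fast")
  if (any(!is.finite(object@N))) msg <- c(msg, "N must be finite")
  if (any(object@N < 0) && !object@flagNegative)
    msg <- c(msg, "negative components must set flagNegative")
  if (length(msg)) msg else TRUE
})

#' Per-region and per-component neutron dose breakdown for one location
#'
#' Biologically weighted neutron dose Dn = sum_j N_j Dsim_j together with its
#' two consistent partitions (by energy region and by boron/nitrogen/hydrogen
#' component) and the corresponding unweighted absorbed dose.
#'
#' @slot locationId body location identifier
#' @slot perRegion weighted dose by energy region, Gy-eq
#' @slot perComponent weighted dose by component (boron, nitrogen,
#'   hydrogen), Gy-eq
#' @slot total total weighted neutron dose Dn, Gy-eq
#' @slot absorbedPerRegion unweighted absorbed dose by region, Gy
#' @slot absorbedTotal total unweighted neutron absorbed dose, Gy
#' @seealso [neutronEquivalentDose()]
#' @export
setClass("NeutronDoseBreakdown",
  representation(locationId = "character", perRegion = "numeric",
                 perComponent = "numeric", total = "numeric",
                 absorbedPerRegion = "numeric", absorbedTotal = "numeric"))

setValidity("NeutronDoseBreakdown", function(object) {
  msg <- character()
  tol <- 1e-10 * max(1, abs(object@total))
  if (abs(sum(object@perRegion) - object@total) > tol)
    msg <- c(msg, "region partition must sum to the total")
  if (abs(sum(object@perComponent) - object@total) > tol)
    msg <- c(msg, "component partition must sum to the total")
  if (length(msg)) msg else TRUE
})

#' Cohort dose results as a SummarizedExperiment
#'
#' Rows are body locations, columns are patients; assays hold the per
#' patient-by-location dose quantities (gamma, neutron absorbed, total
#' absorbed, biologically weighted dose, H*(10), EQD2-normalized metrics,
#' weighted component doses and unfolded normalization factors). Patient
#' covariates (blood boron, prescription, treatment-site group) live in
#' \code{colData}; location distances in \code{rowData}; per-measurement QA
#' (condition numbers, flags) in \code{metadata()$qa}.
#'
#' @seealso [analyzeCohort()], [summarizeCohort()]
#' @export
setClass("DoseExperiment", contains = "SummarizedExperiment")

.DOSE_ASSAYS <- c("gammaDose", "neutronAbsorbed", "totalAbsorbed",
                  "weightedDose", "neutronHStar", "hStar", "eqd2Weighted",
                  "hStarPerEqd2", "eqd2PerEqd2",
                  "boronWeighted", "nitrogenWeighted", "hydrogenWeighted",
                  "nThermal", "nEpithermal", "nFast")

setValidity("DoseExperiment", function(object) {
  missing <- setdiff(.DOSE_ASSAYS, SummarizedExperiment::assayNames(object))
  if (length(missing))
    paste("missing assays:", paste(missing, collapse = ", "))
  else TRUE
})
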