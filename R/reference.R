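#' Reference model configuration
#'
#' Reads the parametric reference-room configuration: per-component spectrum
#' amplitudes and attenuation lengths, treatment charge, per-location
#' distances, gamma doses and primary gamma fractions. The shipped defaults
#' place six measurement locations (neck, chest, abdomen, waist, knee,
#' ankle) at increasing lateral distance from the irradiation field; only
#' the waist offset (~65 cm) is anchored, the others are editable
#' placeholders (see the config comments).
#'
#' @param path optional path to an alternative configuration JSON
#' @return configuration list
#' @export
referenceConfig <- function(path = NULL) {
  if (is.null(path)) path <- extdataFile("reference_config.json")
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg$amplitude_per_C <- lapply(cfg$amplitude_per_C, as.numeric)
  cfg$attenuation_cm <- lapply(cfg$attenuation_cm, as.numeric)
  cfg
}

#' Build the reference record for one location
#'
#' Assembles a [ReferenceLocation-class]: the 3x3 foil-by-region response
#' matrix (folding the location spectrum with each foil cross section per
#' region), the per-region boron / nitrogen / hydrogen physical dose
#' components per treatment (boron at the 25 ppm reference concentration),
#' per-region H*(10) per treatment, and the configured gamma dose with its
#' primary fraction.
#'
#' @param loc per-location config entry (id, distance_cm, gamma_Gy,
#'   gamma_primary_fraction)
#' @param grid an [EnergyGrid-class]
#' @param xsList named list of [CrossSectionTable-class] for Au, Mn, Al
#' @param hCoeffs table from [ambientDoseCoefficients()]
#' @param kermaList named list of kerma tables (boron, nitrogen, hydrogen)
#' @param config reference configuration from [referenceConfig()]
#' @return a [ReferenceLocation-class]
#' @export
buildReferenceRecord <- function(loc, grid = defaultEnergyGrid(),
                                 xsList = NULL, hCoeffs = NULL,
                                 kermaList = NULL,
                                 config = referenceConfig()) {
  if (is.null(xsList))
    xsList <- lapply(stats::setNames(nm = FOILS), groupAverageSigma, grid = grid)
  if (is.null(hCoeffs)) hCoeffs <- ambientDoseCoefficients()
  if (is.null(kermaList))
    kermaList <- lapply(stats::setNames(nm = c("boron", "nitrogen", "hydrogen")),
                        kermaCoefficients)
  sp <- spectrumAtDistance(loc$id, loc$distance_cm, grid, config)
  Q <- config$charge_per_treatment_C

  Rsim <- matrix(0, 3, 3, dimnames = list(FOILS, REGIONS))
  for (f in FOILS) for (r in REGIONS)
    Rsim[f, r] <- foldReactionRate(sp, xsList[[f]], r)

  Dref <- matrix(0, 3, 3, dimnames = list(c("boron", "nitrogen", "hydrogen"),
                                          REGIONS))
  for (comp in rownames(Dref)) for (r in REGIONS)
    Dref[comp, r] <- foldDose(sp, kermaList[[comp]], r, charge = Q)

  Href <- vapply(REGIONS, function(r) foldHStar(sp, hCoeffs, r, charge = Q),
                 numeric(1))

  new("ReferenceLocation", locationId = loc$id,
      distanceCm = as.numeric(loc$distance_cm),
      distanceEdgeCm = as.numeric(loc$distance_cm) -
        as.numeric(config$field_edge_offset_cm),
      Rsim = Rsim, Dref = Dref, Href = Href,
      gammaGy = as.numeric(loc$gamma_Gy),
      gammaPrimaryFraction = as.numeric(loc$gamma_primary_fraction))
}

#' Build the full reference library
#'
#' Folds the parametric reference model at every configured location.
#'
#' @param config reference configuration from [referenceConfig()]
#' @param grid an [EnergyGrid-class]
#' @return a [ReferenceLibrary-class]
#' @export
buildReferenceLibrary <- function(config = referenceConfig(),
                                  grid = defaultEnergyGrid()) {
  xsList <- lapply(stats::setNames(nm = FOILS), groupAverageSigma, grid = grid)
  hCoeffs <- ambientDoseCoefficients()
  kermaList <- lapply(stats::setNames(nm = c("boron", "nitrogen", "hydrogen")),
                      kermaCoefficients)
  locs <- lapply(config$locations, buildReferenceRecord, grid = grid,
                 xsList = xsList, hCoeffs = hCoeffs, kermaList = kermaList,
                 config = config)
  new("ReferenceLibrary", locations = locs, gridEdges = grid@edges,
      chargeC = as.numeric(config$charge_per_treatment_C),
      fieldEdgeOffsetCm = as.numeric(config$field_edge_offset_cm),
      schemaVersion = 1L)
}

#' Serialize / deserialize a reference library as JSON
#'
#' The JSON schema is the integration contract: installations with a genuine
#' Monte Carlo room model can export their response matrices, dose
#' components and H*(10) values in this schema and use the rest of the
#' pipeline unchanged.
#'
#' @param lib a [ReferenceLibrary-class]
#' @param path output (or input) JSON path
#' @return `writeReferenceLibrary` returns `path` invisibly;
#'   `readReferenceLibrary` returns a [ReferenceLibrary-class]
#' @export
writeReferenceLibrary <- function(lib, path) {
  doc <- list(
    schema_version = lib@schemaVersion,
    charge_per_treatment_C = lib@chargeC,
    field_edge_offset_cm = lib@fieldEdgeOffsetCm,
    grid_edges_MeV = lib@gridEdges,
    locations = lapply(lib@locations, function(l) list(
      id = l@locationId,
      distance_cm = l@distanceCm,
      distance_edge_cm = l@distanceEdgeCm,
      R_sim = as.list(as.data.frame(l@Rsim)),
      D_ref = as.list(as.data.frame(l@Dref)),
      H_ref = as.list(l@Href),
      gamma_Gy = l@gammaGy,
      gamma_primary_fraction = l@gammaPrimaryFraction)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeReferenceLibrary
#' @export
readReferenceLibrary <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  locs <- lapply(seq_len(nrow(doc$locations)), function(i) {
    l <- doc$locations[i, ]
    Rsim <- matrix(unlist(l$R_sim), 3, 3, dimnames = list(FOILS, REGIONS))
    Dref <- matrix(unlist(l$D_ref), 3, 3,
                   dimnames = list(c("boron", "nitrogen", "hydrogen"), REGIONS))
    new("ReferenceLocation", locationId = l$id,
        distanceCm = l$distance_cm, distanceEdgeCm = l$distance_edge_cm,
        Rsim = Rsim, Dref = Dref,
        Href = stats::setNames(unlist(l$H_ref), REGIONS),
        gammaGy = l$gamma_Gy,
        gammaPrimaryFraction = l$gamma_primary_fraction)
  })
  new("ReferenceLibrary", locations = locs,
      gridEdges = doc$grid_edges_MeV, chargeC = doc$charge_per_treatment_C,
      fieldEdgeOffsetCm = doc$field_edge_offset_cm,
      schemaVersion = as.integer(doc$schema_version))
}
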