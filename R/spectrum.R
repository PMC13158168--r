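#' Build a parametric multigroup neutron spectrum
#'
#' Synthesizes a location spectrum as the sum of three normalized shapes: a
#' thermal Maxwellian fluence spectrum (kT = 2.53e-8 MeV by default), a 1/E
#' epithermal slope confined between the two region cut energies, and an
#' exponential fast tail above the epithermal cut. Each shape is integrated
#' analytically onto the fine grid and scaled by its amplitude (total
#' component fluence per unit beam charge, n/cm2/C).
#'
#' @param locationId body location identifier
#' @param grid an [EnergyGrid-class]
#' @param thermal,epithermal,fast component amplitudes, n/cm2/C (>= 0)
#' @param kT Maxwellian temperature in MeV
#' @param fastE0 e-folding energy of the fast tail, MeV
#' @return a [NeutronSpectrum-class]
#' @export
buildSpectrum <- function(locationId, grid = defaultEnergyGrid(),
                          thermal = 0, epithermal = 0, fast = 0,
                          kT = 2.53e-8, fastE0 = 0.5) {
  if (thermal < 0 || epithermal < 0 || fast < 0)
    stop("component amplitudes must be >= 0")
  if (kT <= 0 || fastE0 <= 0)
    stop("kT and fastE0 must be > 0")
  e <- grid@edges
  b <- grid@regionBounds
  emax <- e[length(e)]

  # Maxwellian fluence spectrum phi(E) ~ E exp(-E/kT): gamma(shape=2) CDF
  pm <- stats::pgamma(e, shape = 2, scale = kT)
  phi_th <- diff(pm) / (pm[length(pm)] - pm[1])

  # 1/E between the two cuts
  lo <- pmax(e[-length(e)], b[1]); hi <- pmin(e[-1], b[2])
  phi_epi <- pmax(0, log(pmax(hi / lo, 1))) / log(b[2] / b[1])

  # exponential tail on (cut2, Emax]
  pe <- stats::pexp(pmax(pmin(e, emax), b[2]), rate = 1 / fastE0)
  norm <- stats::pexp(emax, 1 / fastE0) - stats::pexp(b[2], 1 / fastE0)
  phi_fast <- diff(pe) / norm

  new("NeutronSpectrum", locationId = locationId, grid = grid,
      fluence = thermal * phi_th + epithermal * phi_epi + fast * phi_fast)
}

#' Spectrum at a lateral distance from the field center
#'
#' Evaluates the parametric reference model: each component amplitude decays
#' exponentially with distance with its own attenuation length (thermal
#' shortest by default, so the spectrum hardens with distance).
#'
#' @param locationId body location identifier
#' @param distance lateral distance from the field center, cm
#' @param grid an [EnergyGrid-class]
#' @param config reference configuration list from [referenceConfig()]
#' @return a [NeutronSpectrum-class]
#' @export
spectrumAtDistance <- function(locationId, distance,
                               grid = defaultEnergyGrid(),
                               config = referenceConfig()) {
  if (distance < 0) stop("distance must be >= 0")
  A <- config$amplitude_per_C
  L <- config$attenuation_cm
  if (any(unlist(A) < 0) || any(unlist(L) <= 0))
    stop("amplitudes must be >= 0 and attenuation lengths > 0")
  buildSpectrum(locationId, grid,
                thermal = A$thermal * exp(-distance / L$thermal),
                epithermal = A$epithermal * exp(-distance / L$epithermal),
                fast = A$fast * exp(-distance / L$fast),
                kT = config$kT_MeV, fastE0 = config$fast_E0_MeV)
}

.regionMask <- function(grid, region) {
  region <- match.arg(region, c("all", REGIONS))
  if (region == "all") rep(TRUE, nGroups(grid)) else
    grid@regionOfGroup == region
}

.checkSameGrid <- function(spectrum, n) {
  if (nGroups(spectrum@grid) != n)
    stop("spectrum and cross-section table are on different grids")
}

#' Fold a spectrum with a foil cross section
#'
#' Per-region (or total) reaction rate per atom per unit beam charge:
#' sum over the selected fine groups of fluence times the group cross
#' section, with barns converted to cm2. Region-filtered values are
#' partition-additive: the three region values sum to the "all" value.
#'
#' @param spectrum a [NeutronSpectrum-class]
#' @param xs a [CrossSectionTable-class] on the same grid
#' @param region "all" (default), "thermal", "epithermal" or "fast"
#' @return reaction rate in n/C/atom
#' @export
foldReactionRate <- function(spectrum, xs, region = "all") {
  .checkSameGrid(spectrum, length(xs@sigma))
  m <- .regionMask(spectrum@grid, region)
  sum(spectrum@fluence[m] * xs@sigma[m] * BARN_CM2)
}

#' Fold a spectrum with H*(10) conversion coefficients
#'
#' Ambient dose equivalent per treatment: sum over the selected groups of
#' fluence times the coefficient interpolated (log-log) at the group
#' midpoint, converted pSv to Sv and scaled by the delivered beam charge.
#'
#' @param spectrum a [NeutronSpectrum-class] (fluence per unit charge)
#' @param coeffs coefficient table from [ambientDoseCoefficients()]
#' @param region "all" (default) or one region label
#' @param charge delivered beam charge per treatment, C (default 1)
#' @return H*(10) in Sv
#' @export
foldHStar <- function(spectrum, coeffs = ambientDoseCoefficients(),
                      region = "all", charge = 1) {
  stopifnotScalar(charge, "charge")
  m <- .regionMask(spectrum@grid, region)
  mids <- gridMidpoints(spectrum@grid)[m]
  h <- interpolateHStar(mids, coeffs)
  sum(spectrum@fluence[m] * h) * PSV_SV * charge
}

#' Fold a spectrum with a tissue kerma coefficient table
#'
#' Physical dose per treatment for one dose component: sum over the selected
#' groups of fluence times the kerma coefficient (Gy cm2) interpolated
#' log-log at the group midpoint, scaled by the delivered charge.
#'
#' @param spectrum a [NeutronSpectrum-class] (fluence per unit charge)
#' @param kerma table from [kermaCoefficients()]
#' @param region "all" (default) or one region label
#' @param charge delivered beam charge per treatment, C (default 1)
#' @return absorbed dose in Gy
#' @export
foldDose <- function(spectrum, kerma, region = "all", charge = 1) {
  stopifnotScalar(charge, "charge")
  m <- .regionMask(spectrum@grid, region)
  mids <- gridMidpoints(spectrum@grid)[m]
  k <- evalLogLog(mids, kerma$energy_MeV, kerma$kerma)
  sum(spectrum@fluence[m] * k) * charge
}
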