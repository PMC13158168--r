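#' Construct a multigroup energy grid
#'
#' Builds an [EnergyGrid-class] from explicit edges, snapping is not
#' performed here: the two region cut energies (5.3e-7 and 1e-2 MeV) must be
#' present among the edges.
#'
#' @param edges strictly increasing group edges in MeV
#' @return an [EnergyGrid-class]
#' @seealso [defaultEnergyGrid()]
#' @export
energyGrid <- function(edges) {
  bounds <- c(5.3e-7, 1e-2)
  mids <- sqrt(edges[-length(edges)] * edges[-1])
  region <- ifelse(mids <= bounds[1], "thermal",
                   ifelse(mids <= bounds[2], "epithermal", "fast"))
  new("EnergyGrid", edges = edges, regionBounds = bounds,
      regionOfGroup = region)
}

#' Default fine energy grid
#'
#' 60 logarithmically spaced edges from 1e-20 to 30 MeV with the edges
#' nearest to the two region cuts snapped exactly onto 5.3e-7 and 1e-2 MeV,
#' so region boundaries land exactly on the printed cut energies.
#'
#' @param nEdges number of group edges (default 60, i.e. 59 groups)
#' @return an [EnergyGrid-class]
#' @export
defaultEnergyGrid <- function(nEdges = 60L) {
  edges <- 10^seq(-20, log10(30), length.out = nEdges)
  edges[1] <- 1e-20
  edges[nEdges] <- 30
  for (cut in c(5.3e-7, 1e-2)) {
    i <- which.min(abs(log(edges) - log(cut)))
    edges[i] <- cut
  }
  energyGrid(sort(unique(edges)))
}

#' Energy region of a neutron energy
#'
#' Maps an energy to its macroscopic region using upper-inclusive intervals:
#' thermal for E <= 5.3e-7 MeV, epithermal for 5.3e-7 < E <= 1e-2 MeV,
#' fast for 1e-2 < E <= 30 MeV.
#'
#' @param E energy in MeV (vectorized); must lie in (1e-20, 30]
#' @param grid an [EnergyGrid-class] supplying the region cuts
#' @return character vector of region labels
#' @export
regionOfEnergy <- function(E, grid = defaultEnergyGrid()) {
  if (any(E <= 1e-20 | E > 30)) {
    stop("energy outside the (1e-20, 30] MeV domain")
  }
  b <- grid@regionBounds
  ifelse(E <= b[1], "thermal", ifelse(E <= b[2], "epithermal", "fast"))
}

#' Foil nuclear constants
#'
#' Reads the shipped foil specification set (reaction, product half-life,
#' gamma line and intensity, isotopic abundance, atomic mass, geometry,
#' detector efficiency, element mass fraction in the foil alloy). The Mn
#' entry carries the ~13 wt% manganese content of manganin.
#'
#' @param path optional path to an alternative foil-constants JSON document
#' @return named list of per-foil specification lists (Au, Mn, Al)
#' @export
foilSpecs <- function(path = NULL) {
  if (is.null(path)) path <- extdataFile("foil_constants.json")
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- doc$foils
  for (nm in names(specs)) {
    s <- specs[[nm]]
    s$name <- nm
    if (s$half_life_s <= 0) stop("half-life must be > 0 for ", nm)
    if (s$gamma_intensity <= 0 || s$gamma_intensity > 1)
      stop("gamma intensity must be in (0, 1] for ", nm)
    if (s$abundance <= 0 || s$abundance > 1)
      stop("abundance must be in (0, 1] for ", nm)
    if (s$efficiency <= 0 || s$efficiency >= 1)
      stop("detector efficiency must be in (0, 1) for ", nm)
    specs[[nm]] <- s
  }
  expected <- c(Au = 412, Mn = 847, Al = 1369)
  for (nm in names(expected)) {
    if (!isTRUE(all.equal(specs[[nm]]$gamma_line_keV, expected[[nm]])))
      stop("gamma line for ", nm, " must be ", expected[[nm]], " keV")
  }
  specs
}

#' Biology and weighting constants of the dose model
#'
#' CBE for skin (boron component), RBE for the nitrogen and hydrogen
#' components, the 25 ppm reference blood-boron concentration, the
#' tumor-to-blood boron ratio and tumor CBE used to synthesize tumor doses,
#' the linear-quadratic alpha/beta ratios, and the gamma Gy-to-Sv factor
#' (exactly 1).
#'
#' @param path optional path to an alternative constants JSON document
#' @return named list of constants
#' @export
biologyConstants <- function(path = NULL) {
  if (is.null(path)) path <- extdataFile("foil_constants.json")
  b <- jsonlite::read_json(path, simplifyVector = TRUE)$biology
  if (any(unlist(b) <= 0)) stop("all biology constants must be > 0")
  b
}

#' ICRU soft-tissue elemental composition
#'
#' @param path optional path to an alternative constants JSON document
#' @return named numeric vector of element mass fractions (H, C, N, O)
#' @export
tissueComposition <- function(path = NULL) {
  if (is.null(path)) path <- extdataFile("foil_constants.json")
  w <- unlist(jsonlite::read_json(path, simplifyVector = TRUE)$tissue)
  if (abs(sum(w) - 1) > 1e-3) stop("tissue mass fractions must sum to 1")
  w
}

#' Neutron fluence-to-H*(10) conversion coefficients
#'
#' Loads the tabulated ICRP Publication 74 style neutron ambient dose
#' equivalent coefficients (pSv cm2 per unit fluence).
#'
#' @param path optional path to an alternative two-column CSV
#'   (energy_MeV, h_star)
#' @return data.frame with columns energy_MeV and h_star
#' @export
ambientDoseCoefficients <- function(path = NULL) {
  if (is.null(path)) path <- extdataFile("h_star_neutron.csv")
  df <- readEnergyTable(path, "h_star")
  if (any(df$h_star <= 0)) stop("H*(10) coefficients must be > 0")
  df
}

#' Interpolate the H*(10) coefficient at an energy
#'
#' Log-log interpolation between adjacent tabulated points, the standard
#' convention for neutron conversion coefficients; exact at tabulated
#' energies. Energies outside the table raise an error (no clamping).
#'
#' @param E energy in MeV (vectorized)
#' @param coeffs coefficient table from [ambientDoseCoefficients()]
#' @return pSv cm2 per unit fluence at each energy
#' @export
interpolateHStar <- function(E, coeffs = ambientDoseCoefficients()) {
  evalLogLog(E, coeffs$energy_MeV, coeffs$h_star)
}

#' Load a pointwise cross-section table
#'
#' @param foil "Au", "Mn" or "Al" to load the shipped table, or the path of a
#'   two-column CSV (energy_MeV, sigma_barns)
#' @return data.frame with columns energy_MeV and sigma
#' @export
pointwiseSigma <- function(foil) {
  files <- c(Au = "xs_au197_ng.csv", Mn = "xs_mn55_ng.csv",
             Al = "xs_al27_na.csv")
  path <- if (foil %in% names(files)) extdataFile(files[[foil]]) else foil
  df <- readEnergyTable(path, "sigma")
  if (any(df$sigma < 0)) stop("cross sections must be >= 0")
  df
}

# integral of sigma dE/E over [a, b] inside one table segment, where the
# interpolation rule is log-log (piecewise power law) when both segment
# endpoints are positive and linear-in-E otherwise
.segmentLethargyIntegral <- function(a, b, s1, s2, loglog) {
  if (s1 == 0 && s2 == 0) return(0)
  if (loglog) {
    p <- log(s2 / s1) / log(b / a)              # sigma = s1 (E/a)^p
    if (abs(p) < 1e-12) return(s1 * log(b / a))
    s1 * ((b / a)^p - 1) / p
  } else {
    c1 <- (s2 - s1) / (b - a)
    c0 <- s1 - c1 * a
    c0 * log(b / a) + c1 * (b - a)
  }
}

#' Lethargy-weighted group-average cross sections
#'
#' Averages a pointwise cross section onto an [EnergyGrid-class] with a flat
#' (flux-weight-free) lethargy weighting: for each group, the integral of
#' sigma(E) dE/E divided by the group lethargy width. The pointwise table is
#' interpolated log-log between points (exactly reproducing 1/v and other
#' power-law shapes) and linearly across segments touching zero (threshold
#' reactions), so groups entirely below a threshold average to exactly zero.
#'
#' @param foil foil name ("Au", "Mn", "Al") used to label the result
#' @param grid an [EnergyGrid-class]
#' @param pointwise pointwise table from [pointwiseSigma()]; defaults to the
#'   shipped table for `foil`
#' @return a [CrossSectionTable-class]
#' @export
groupAverageSigma <- function(foil, grid = defaultEnergyGrid(),
                              pointwise = pointwiseSigma(foil)) {
  E <- pointwise$energy_MeV
  S <- pointwise$sigma
  edges <- grid@edges
  if (edges[1] < E[1] || edges[length(edges)] > E[length(E)]) {
    lo <- which(edges < E[1])
    hi <- which(edges > E[length(E)])
    stop("pointwise data does not cover grid groups: edges ",
         paste(unique(c(lo, hi)), collapse = ", "))
  }
  ng <- length(edges) - 1L
  sigma <- numeric(ng)
  for (g in seq_len(ng)) {
    a <- edges[g]; b <- edges[g + 1]
    knots <- sort(unique(c(a, b, E[E > a & E < b])))
    tot <- 0
    for (k in seq_len(length(knots) - 1L)) {
      x1 <- knots[k]; x2 <- knots[k + 1]
      seg <- findInterval(sqrt(x1 * x2), E)
      e1 <- E[seg]; e2 <- E[seg + 1]
      t1 <- S[seg]; t2 <- S[seg + 1]
      loglog <- t1 > 0 && t2 > 0
      if (loglog) {
        p <- log(t2 / t1) / log(e2 / e1)
        s1 <- t1 * (x1 / e1)^p
        s2 <- t1 * (x2 / e1)^p
      } else {
        s1 <- t1 + (t2 - t1) * (x1 - e1) / (e2 - e1)
        s2 <- t1 + (t2 - t1) * (x2 - e1) / (e2 - e1)
      }
      tot <- tot + .segmentLethargyIntegral(x1, x2, s1, s2, loglog)
    }
    sigma[g] <- tot / log(b / a)
  }
  sigma[abs(sigma) < 1e-300] <- 0
  new("CrossSectionTable", foil = foil, sigma = sigma)
}

#' Tissue kerma coefficient tables
#'
#' Loads the shipped per-component dose-response coefficients (Gy cm2 per
#' unit fluence) for ICRU soft tissue: boron capture at the 25 ppm reference
#' concentration, nitrogen capture, and hydrogen elastic recoil.
#'
#' @param component "boron", "nitrogen" or "hydrogen", or a CSV path
#' @return data.frame with columns energy_MeV and kerma
#' @export
kermaCoefficients <- function(component) {
  files <- c(boron = "kerma_boron_25ppm.csv", nitrogen = "kerma_nitrogen.csv",
             hydrogen = "kerma_hydrogen.csv")
  path <- if (component %in% names(files)) extdataFile(files[[component]])
          else component
  readEnergyTable(path, "kerma")
}
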