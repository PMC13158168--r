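# shared fixtures: coarse test grid, hand-built spectra and references

REGIONS <- c("thermal", "epithermal", "fast")
FOILS <- c("Au", "Mn", "Al")

# coarse grid whose edges include both region cuts; groups:
# (1e-20,1e-10], (1e-10,5.3e-7] thermal; (5.3e-7,1e-4], (1e-4,1e-2] epi;
# (1e-2,0.5], (0.5,2], (2,30] fast
coarseGrid <- function() {
  energyGrid(c(1e-20, 1e-10, 5.3e-7, 1e-4, 1e-2, 0.5, 2, 30))
}

# spectrum with explicit group fluences on a grid
handSpectrum <- function(grid, fluence, id = "hand") {
  new("NeutronSpectrum", locationId = id, grid = grid, fluence = fluence)
}

# minimal valid reference location with controllable dose data
handReference <- function(Dref = NULL, Href = c(1, 1, 1), gammaGy = 0.1,
                          primary = 0.5, Rsim = NULL) {
  if (is.null(Rsim)) {
    Rsim <- matrix(c(2, 1, 0,  1, 0.2, 0,  0.05, 0.1, 4), 3, 3,
                   dimnames = list(FOILS, REGIONS))
  }
  if (is.null(Dref)) {
    Dref <- matrix(0, 3, 3, dimnames = list(c("boron", "nitrogen", "hydrogen"),
                                            REGIONS))
    Dref[, "thermal"] <- c(0.1, 0.05, 0.02)
  }
  new("ReferenceLocation", locationId = "test", distanceCm = 10,
      distanceEdgeCm = 2.5, Rsim = Rsim, Dref = Dref,
      Href = stats::setNames(Href, REGIONS), gammaGy = gammaGy,
      gammaPrimaryFraction = primary)
}

unitFactors <- function(N = c(1, 1, 1), id = "test") {
  new("NormalizationFactors", locationId = id,
      N = stats::setNames(as.numeric(N), REGIONS),
      nSd = rep(NA_real_, 3), conditionNumber = 1,
      flagNegative = any(N < 0), flagIllConditioned = FALSE)
}

# memoized default reference library (built once per test run)
.libCache <- new.env()
getTestLib <- function() {
  if (is.null(.libCache$lib)) .libCache$lib <- buildReferenceLibrary()
  .libCache$lib
}
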