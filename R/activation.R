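#' Number of target atoms in a foil
#'
#' Atoms of the target isotope: mass times the element mass fraction in the
#' foil alloy (e.g. the ~13 wt% manganese content of manganin), divided by
#' the atomic mass, times Avogadro's number and the isotopic abundance.
#'
#' @param spec a foil specification from [foilSpecs()]
#' @param mass foil mass in g
#' @return number of target atoms
#' @export
atomsInFoil <- function(spec, mass) {
  stopifnotScalar(mass, "mass")
  mass * spec$element_mass_fraction / spec$atomic_mass_g_mol *
    AVOGADRO * spec$abundance
}

#' Activation saturation factor
#'
#' Fraction of equilibrium activity reached after irradiating for `tIrr`
#' under constant beam current: 1 - exp(-lambda tIrr), lambda = ln2 / T1/2.
#'
#' @param halfLife product half-life, s
#' @param tIrr irradiation duration, s
#' @return fraction in (0, 1)
#' @export
saturationFactor <- function(halfLife, tIrr) {
  stopifnotScalar(halfLife, "halfLife")
  stopifnotScalar(tIrr, "tIrr")
  -expm1(-log(2) / halfLife * tIrr)
}

#' Reaction rate from HPGe net peak counts
#'
#' Standard activation-analysis conversion under the constant-current
#' assumption. The per-atom, per-second reaction rate is
#' \deqn{r = C \lambda / [N \epsilon I (1 - e^{-\lambda t_{irr}})
#'   e^{-\lambda t_{cool}} (1 - e^{-\lambda t_{count}})]}
#' and the reported quantity is the rate per unit delivered beam charge,
#' R = r t_irr / Q (n/C/atom). Negative net counts (background
#' over-subtraction, realistic for the Al foil far from the field) are
#' clamped to zero with a warning. An optional multiplicative `correction`
#' (default 1) accommodates institutional geometry/self-absorption factors.
#'
#' @param counts net full-energy-peak counts
#' @param spec foil specification from [foilSpecs()]
#' @param tIrr,tCool,tCount irradiation, cooling and counting (live) times, s
#' @param charge delivered beam charge, C
#' @param mass foil mass, g
#' @param correction optional multiplicative correction factor
#' @return reaction rate in n/C/atom
#' @export
reactionRateFromCounts <- function(counts, spec, tIrr, tCool, tCount,
                                   charge, mass, correction = 1) {
  for (v in c(tIrr = tIrr, tCool = tCool, tCount = tCount)) {
    if (!is.finite(v) || v <= 0) stop("durations must be > 0")
  }
  stopifnotScalar(charge, "charge")
  stopifnotScalar(mass, "mass")
  if (counts < 0) {
    warning("negative net counts clamped to zero (background over-subtraction)")
    counts <- 0
  }
  lambda <- log(2) / spec$half_life_s
  N <- atomsInFoil(spec, mass)
  denom <- N * spec$efficiency * spec$gamma_intensity *
    (-expm1(-lambda * tIrr)) * exp(-lambda * tCool) *
    (-expm1(-lambda * tCount))
  if (denom <= 0 || !is.finite(denom))
    stop("degenerate timing/spec factors: zero denominator")
  r <- counts * lambda / denom
  r * tIrr / charge * correction
}

#' Net counts expected from a known reaction rate
#'
#' Exact inverse of [reactionRateFromCounts()]; used to synthesize counting
#' records for cohort simulation and round-trip validation.
#'
#' @inheritParams reactionRateFromCounts
#' @param rate reaction rate in n/C/atom
#' @return expected net peak counts (not rounded)
#' @export
countsFromReactionRate <- function(rate, spec, tIrr, tCool, tCount,
                                   charge, mass, correction = 1) {
  if (rate < 0) stop("reaction rate must be >= 0")
  lambda <- log(2) / spec$half_life_s
  N <- atomsInFoil(spec, mass)
  denom <- N * spec$efficiency * spec$gamma_intensity *
    (-expm1(-lambda * tIrr)) * exp(-lambda * tCool) *
    (-expm1(-lambda * tCount))
  rate * charge / (tIrr * correction) * denom / lambda
}

MEASUREMENT_COLUMNS <- c("patient_id", "location", "foil", "net_counts",
                         "reaction_rate", "gamma_dose_Gy", "t_irr_s",
                         "t_cool_s", "t_count_s", "charge_C", "foil_mass_g",
                         "boron_ppm", "d95_gy_eq", "n_fractions",
                         "site_group")

#' Read / write per-patient measurement tables
#'
#' Long-format measurement CSV: one row per patient x location x detector.
#' Foil rows (`foil` in Au/Mn/Al) must carry exactly one of `net_counts` or
#' `reaction_rate`; TLD rows (`foil == "TLD"`) carry `gamma_dose_Gy`.
#' Patient covariates (blood boron concentration, D95 prescription,
#' fraction number, treatment-site group) are repeated on each row.
#'
#' @param path CSV path
#' @return data.frame of measurements
#' @export
readMeasurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing))
    stop("measurement file lacks columns: ", paste(missing, collapse = ", "))
  foil_rows <- df$foil %in% FOILS
  both <- foil_rows & !is.na(df$net_counts) & !is.na(df$reaction_rate)
  neither <- foil_rows & is.na(df$net_counts) & is.na(df$reaction_rate)
  if (any(both) || any(neither))
    stop("each foil row must carry exactly one of net_counts / reaction_rate")
  df
}

#' @rdname readMeasurements
#' @param df measurement data.frame
#' @export
writeMeasurements <- function(df, path) {
  utils::write.csv(df[, MEASUREMENT_COLUMNS], path, row.names = FALSE)
  invisible(path)
}
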