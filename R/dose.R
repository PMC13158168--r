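#' Combine neutron and gamma results into total doses
#'
#' Biologically weighted total = Dn + gamma (gamma weight exactly 1);
#' absorbed total = unweighted neutron absorbed + gamma; total H*(10) =
#' neutron H*(10) + gamma dose taken as Sv (1 Gy = 1 Sv for gamma rays).
#'
#' @param neutron a [NeutronDoseBreakdown-class]
#' @param neutronHStar neutron H*(10), Sv (from [patientHStar()])
#' @param gammaGy measured gamma absorbed dose, Gy (>= 0)
#' @param constants constants list from [biologyConstants()]
#' @return named list: gammaDose, neutronAbsorbed, totalAbsorbed,
#'   weightedDose, neutronHStar, hStar, plus the weighted component vector
#' @export
totalDoses <- function(neutron, neutronHStar, gammaGy,
                       constants = biologyConstants()) {
  if (gammaGy < 0) stop("gamma dose must be >= 0")
  list(
    gammaDose = gammaGy,
    neutronAbsorbed = neutron@absorbedTotal,
    totalAbsorbed = neutron@absorbedTotal + gammaGy,
    weightedDose = neutron@total + gammaGy,
    neutronHStar = neutronHStar,
    hStar = neutronHStar + gammaGy * constants$gamma_Sv_per_Gy,
    weightedComponents = neutron@perComponent)
}

#' Equieffective dose in 2 Gy fractions (linear-quadratic model)
#'
#' EQD2 = n d (d + alpha/beta) / (2 + alpha/beta). Exact fixed point at
#' d = 2 Gy (EQD2 = n d for any alpha/beta).
#'
#' @param n number of fractions (>= 1)
#' @param d dose per fraction, Gy (>= 0); vectorized
#' @param alphaBeta alpha/beta ratio, Gy (> 0)
#' @return EQD2 in Gy
#' @export
eqd2 <- function(n, d, alphaBeta) {
  if (any(alphaBeta <= 0)) stop("alpha/beta must be > 0")
  if (any(n < 1)) stop("number of fractions must be >= 1")
  if (any(d < 0)) stop("dose per fraction must be >= 0")
  n * d * (d + alphaBeta) / (2 + alphaBeta)
}

#' EQD2-normalized out-of-field metrics
#'
#' Normalizes a location result to the tumor prescription for
#' inter-modality (TG-158-style) comparison. The denominator is the EQD2 of
#' the D95 prescription (alpha/beta = 10 Gy for tumor). Metric 1 divides
#' the total H*(10) directly (the operational quantity is not
#' EQD2-converted); metric 2 first converts the location weighted dose to
#' EQD2 with alpha/beta = 2 Gy, treating the single BNCT session as one
#' fraction. By default the gamma component is included in the weighted
#' dose entering metric 2; `neutronOnly = TRUE` uses the neutron dose alone.
#'
#' @param totals result list from [totalDoses()]
#' @param d95 prescription D95 weighted dose per fraction, Gy-eq (> 0)
#' @param nFractions number of prescription fractions (default 1)
#' @param constants constants list from [biologyConstants()]
#' @param neutronOnly exclude gamma from the EQD2-converted numerator
#' @return `totals` extended with tumorEqd2, eqd2Weighted, hStarPerEqd2
#'   (Sv/Gy-eq) and eqd2PerEqd2 (dimensionless)
#' @export
normalizedMetrics <- function(totals, d95, nFractions = 1,
                              constants = biologyConstants(),
                              neutronOnly = FALSE) {
  stopifnotScalar(d95, "d95")
  tumorEqd2 <- eqd2(nFractions, d95, constants$alpha_beta_tumor_Gy)
  if (tumorEqd2 <= 0) stop("tumor EQD2 must be > 0")
  numerator <- if (neutronOnly) totals$weightedDose - totals$gammaDose
               else totals$weightedDose
  totals$tumorEqd2 <- tumorEqd2
  totals$eqd2Weighted <- eqd2(1, max(numerator, 0),
                              constants$alpha_beta_normal_Gy)
  totals$hStarPerEqd2 <- totals$hStar / tumorEqd2
  totals$eqd2PerEqd2 <- totals$eqd2Weighted / tumorEqd2
  totals
}

#' Tumor boron weighted dose from a blood-basis physical dose
#'
#' Tumor weighted boron dose = blood-basis physical boron dose x
#' tumor-to-blood ratio (2.5) x tumor CBE (3.8). Used only to synthesize a
#' D95 prescription for cohort simulation; the pipeline never computes
#' in-field tumor dose distributions.
#'
#' @param basisGy physical boron dose basis at the blood concentration, Gy
#' @param constants constants list from [biologyConstants()]
#' @return tumor weighted dose in Gy-eq
#' @export
tumorWeightedDose <- function(basisGy, constants = biologyConstants()) {
  if (any(basisGy < 0)) stop("dose basis must be >= 0")
  basisGy * constants$tumor_blood_ratio * constants$CBE_tumor
}
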