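#' Synthetic cohort specification
#'
#' Study-condition parameters for the synthetic patient generator. Defaults
#' emulate the clinical cohort the workflow is designed for: 271 patients,
#' six measurement locations, blood boron around 25 ppm, a single-session
#' prescription, and multiplicative measurement noise with the largest
#' relative SD on the Al foil (whose counts are near background far from
#' the field).
#'
#' @param nPatients cohort size (default 271)
#' @param seed integer random seed (identical spec + seed gives an
#'   identical cohort)
#' @param nfMeanlog,nfSdlog per-region log-normal location and scale of the
#'   true normalization factors
#' @param rateSd per-foil relative SD of multiplicative reaction-rate noise
#' @param tldSd relative SD of TLD gamma-dose noise
#' @param gammaPatientSdlog patient-to-patient log-scale spread of the true
#'   gamma dose around the location reference
#' @param boronMeanPpm,boronSdlog blood boron-10 distribution (log-normal,
#'   mean `boronMeanPpm`)
#' @param d95Meanlog,d95Sdlog log-normal D95 prescription distribution,
#'   Gy-eq
#' @param nFractions fractions per prescription (default 1, single-session)
#' @param siteMix treatment-site category probabilities (must sum to 1)
#' @param mode emit foil rows as pre-converted reaction rates ("rate") or
#'   as synthesized HPGe counting records ("counts")
#' @return validated spec list of class `cohortSpec`
#' @export
cohortSpec <- function(nPatients = 271L, seed = 1L,
                       nfMeanlog = c(thermal = 0, epithermal = 0, fast = 0),
                       nfSdlog = c(thermal = 0.15, epithermal = 0.15,
                                   fast = 0.15),
                       rateSd = c(Au = 0.05, Mn = 0.05, Al = 0.15),
                       tldSd = 0.07, gammaPatientSdlog = 0.35,
                       boronMeanPpm = 25, boronSdlog = 0.15,
                       d95Meanlog = log(22), d95Sdlog = 0.25,
                       nFractions = 1L,
                       siteMix = c(nasopharyngeal = 0.35,
                                   oropharyngeal = 0.45,
                                   hypopharyngeal = 0.20),
                       mode = c("rate", "counts")) {
  mode <- match.arg(mode)
  if (nPatients < 1) stop("nPatients must be >= 1")
  if (any(rateSd < 0) || tldSd < 0 || any(nfSdlog < 0) ||
      gammaPatientSdlog < 0)
    stop("all SDs must be >= 0")
  if (abs(sum(siteMix) - 1) > 1e-9) stop("site probabilities must sum to 1")
  if (!all(FOILS %in% names(rateSd))) stop("rateSd must name Au, Mn, Al")
  spec <- list(nPatients = as.integer(nPatients), seed = as.integer(seed),
               nfMeanlog = nfMeanlog, nfSdlog = nfSdlog, rateSd = rateSd,
               tldSd = tldSd, gammaPatientSdlog = gammaPatientSdlog,
               boronMeanPpm = boronMeanPpm, boronSdlog = boronSdlog,
               d95Meanlog = d95Meanlog, d95Sdlog = d95Sdlog,
               nFractions = as.integer(nFractions), siteMix = siteMix,
               mode = mode)
  class(spec) <- "cohortSpec"
  spec
}

# default HPGe counting-session parameters used in "counts" mode
.COUNTING_DEFAULTS <- list(
  t_irr_s = 2400,
  t_cool_s = c(Au = 86400, Mn = 3600, Al = 7200),
  t_count_s = 1800,
  foil_mass_g = c(Au = 0.0758, Mn = 0.1319, Al = 2.121))

#' Generate a synthetic patient cohort with ground truth
#'
#' For every patient and location, draws true per-region normalization
#' factors, computes the noiseless forward measurement R_meas = R_sim N,
#' applies unit-mean multiplicative log-normal noise, draws the true gamma
#' dose around the location reference and its noisy TLD reading, and draws
#' blood boron and a prescription. Emits both the measurement table (all the
#' analysis may see) and a ground-truth table (true factors and doses) for
#' recovery testing; analysis functions never read the truth.
#'
#' @param spec a [cohortSpec()]
#' @param library a [ReferenceLibrary-class]
#' @param constants constants list from [biologyConstants()]
#' @param foils foil specifications from [foilSpecs()] (counts mode)
#' @return list with elements `measurements` and `truth` (data.frames)
#' @export
generateCohort <- function(spec, library = buildReferenceLibrary(),
                           constants = biologyConstants(),
                           foils = foilSpecs()) {
  stopifnot(inherits(spec, "cohortSpec"))
  set.seed(spec$seed)
  ids <- locationIds(library)
  nP <- spec$nPatients
  meas <- vector("list", nP)
  truth <- vector("list", nP)
  bSd <- spec$boronSdlog
  for (p in seq_len(nP)) {
    pid <- sprintf("P%04d", p)
    boron <- if (bSd > 0)
      stats::rlnorm(1, log(spec$boronMeanPpm) - bSd^2 / 2, bSd)
      else spec$boronMeanPpm
    d95 <- stats::rlnorm(1, spec$d95Meanlog, spec$d95Sdlog)
    site <- sample(names(spec$siteMix), 1, prob = spec$siteMix)
    mrows <- vector("list", length(ids))
    trows <- vector("list", length(ids))
    for (li in seq_along(ids)) {
      ref <- library@locations[[li]]
      Ntrue <- stats::setNames(
        stats::rlnorm(3, spec$nfMeanlog[REGIONS], spec$nfSdlog[REGIONS]),
        REGIONS)
      Rtrue <- as.numeric(ref@Rsim %*% Ntrue)
      Rnoisy <- Rtrue * vapply(FOILS, function(f)
        unitMeanLnormFactor(1, spec$rateSd[[f]]), numeric(1))
      gammaTrue <- ref@gammaGy *
        (if (spec$gammaPatientSdlog > 0)
           stats::rlnorm(1, -spec$gammaPatientSdlog^2 / 2,
                         spec$gammaPatientSdlog) else 1)
      gammaMeas <- gammaTrue * unitMeanLnormFactor(1, spec$tldSd)

      nfTrue <- new("NormalizationFactors", locationId = ids[li],
                    N = Ntrue, nSd = rep(NA_real_, 3),
                    conditionNumber = responseCondition(ref@Rsim),
                    flagNegative = FALSE, flagIllConditioned = FALSE)
      bd <- neutronEquivalentDose(nfTrue, ref, boron, constants)
      hN <- patientHStar(nfTrue, ref)

      base <- data.frame(patient_id = pid, location = ids[li],
                         boron_ppm = boron, d95_gy_eq = d95,
                         n_fractions = spec$nFractions, site_group = site,
                         stringsAsFactors = FALSE)
      foil_df <- base[rep(1, 3), ]
      foil_df$foil <- FOILS
      foil_df$gamma_dose_Gy <- NA_real_
      if (spec$mode == "rate") {
        foil_df$net_counts <- NA_real_
        foil_df$reaction_rate <- Rnoisy
        foil_df$t_irr_s <- NA_real_; foil_df$t_cool_s <- NA_real_
        foil_df$t_count_s <- NA_real_; foil_df$charge_C <- NA_real_
        foil_df$foil_mass_g <- NA_real_
      } else {
        cd <- .COUNTING_DEFAULTS
        foil_df$t_irr_s <- cd$t_irr_s
        foil_df$t_cool_s <- cd$t_cool_s[FOILS]
        foil_df$t_count_s <- cd$t_count_s
        foil_df$charge_C <- library@chargeC
        foil_df$foil_mass_g <- cd$foil_mass_g[FOILS]
        foil_df$net_counts <- vapply(seq_len(3), function(i)
          countsFromReactionRate(Rnoisy[i], foils[[FOILS[i]]],
                                 cd$t_irr_s, cd$t_cool_s[[FOILS[i]]],
                                 cd$t_count_s, library@chargeC,
                                 cd$foil_mass_g[[FOILS[i]]]), numeric(1))
        foil_df$reaction_rate <- NA_real_
      }
      tld_df <- base
      tld_df$foil <- "TLD"
      tld_df$net_counts <- NA_real_; tld_df$reaction_rate <- NA_real_
      tld_df$gamma_dose_Gy <- gammaMeas
      tld_df$t_irr_s <- NA_real_; tld_df$t_cool_s <- NA_real_
      tld_df$t_count_s <- NA_real_; tld_df$charge_C <- NA_real_
      tld_df$foil_mass_g <- NA_real_
      mrows[[li]] <- rbind(foil_df, tld_df)

      trows[[li]] <- data.frame(
        patient_id = pid, location = ids[li],
        N_thermal = Ntrue["thermal"], N_epithermal = Ntrue["epithermal"],
        N_fast = Ntrue["fast"],
        boron_ppm = boron, d95_gy_eq = d95, site_group = site,
        gamma_true_Gy = gammaTrue,
        neutron_absorbed_true_Gy = bd@absorbedTotal,
        neutron_weighted_true_GyEq = bd@total,
        weighted_total_true_GyEq = bd@total + gammaTrue,
        neutron_hstar_true_Sv = hN,
        hstar_total_true_Sv = hN + gammaTrue * constants$gamma_Sv_per_Gy,
        stringsAsFactors = FALSE)
    }
    meas[[p]] <- do.call(rbind, mrows)
    truth[[p]] <- do.call(rbind, trows)
  }
  measurements <- do.call(rbind, meas)[, MEASUREMENT_COLUMNS]
  rownames(measurements) <- NULL
  truthDf <- do.call(rbind, truth)
  rownames(truthDf) <- NULL
  list(measurements = measurements, truth = truthDf)
}
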