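#' Analyze a measured cohort against a reference library
#'
#' The full measurement-to-dose pipeline for every patient x location:
#' convert foil counting records to reaction rates where needed, unfold the
#' per-region normalization factors against the location response matrix,
#' scale the reference dose components into the patient neutron equivalent
#' dose and H*(10), add the measured gamma dose, and attach the
#' EQD2-normalized out-of-field metrics. Results are returned as a
#' [DoseExperiment-class] (locations x patients) with per-measurement QA in
#' `metadata()$qa`.
#'
#' @param measurements measurement data.frame (see [readMeasurements()])
#' @param library a [ReferenceLibrary-class]
#' @param constants constants list from [biologyConstants()]
#' @param foils foil specifications from [foilSpecs()]
#' @param clampNegative clamp negative unfolded factors to zero
#' @param condThreshold condition-number threshold for flagging
#' @param scaledHStar scale per-region reference H*(10) by the unfolded
#'   factors (default) or use the unscaled reference value
#' @param neutronOnlyEqd2 exclude gamma from the EQD2-converted metric
#' @return a [DoseExperiment-class]
#' @export
analyzeCohort <- function(measurements, library,
                          constants = biologyConstants(),
                          foils = foilSpecs(),
                          clampNegative = FALSE, condThreshold = 1e6,
                          scaledHStar = TRUE, neutronOnlyEqd2 = FALSE) {
  ids <- locationIds(library)
  pats <- unique(measurements$patient_id)
  nL <- length(ids); nP <- length(pats)
  A <- lapply(stats::setNames(nm = .DOSE_ASSAYS), function(a)
    matrix(NA_real_, nL, nP, dimnames = list(ids, pats)))
  qa <- list()
  colInfo <- data.frame(patient_id = pats, boron_ppm = NA_real_,
                        d95_gy_eq = NA_real_, n_fractions = NA_integer_,
                        site_group = NA_character_, tumorEqd2 = NA_real_,
                        stringsAsFactors = FALSE)

  for (pi in seq_len(nP)) {
    pdf <- measurements[measurements$patient_id == pats[pi], ]
    colInfo$boron_ppm[pi] <- pdf$boron_ppm[1]
    colInfo$d95_gy_eq[pi] <- pdf$d95_gy_eq[1]
    colInfo$n_fractions[pi] <- pdf$n_fractions[1]
    colInfo$site_group[pi] <- pdf$site_group[1]
    for (li in seq_len(nL)) {
      ldf <- pdf[pdf$location == ids[li], ]
      if (!nrow(ldf)) next
      ref <- library@locations[[li]]
      Rmeas <- numeric(3); relUnc <- rep(NA_real_, 3)
      ok <- TRUE
      for (fi in seq_len(3)) {
        row <- ldf[ldf$foil == FOILS[fi], ]
        if (!nrow(row)) { ok <- FALSE; break }
        if (!is.na(row$reaction_rate)) {
          Rmeas[fi] <- row$reaction_rate
        } else {
          Rmeas[fi] <- reactionRateFromCounts(
            row$net_counts, foils[[FOILS[fi]]], row$t_irr_s, row$t_cool_s,
            row$t_count_s, row$charge_C, row$foil_mass_g)
          if (row$net_counts > 0) relUnc[fi] <- 1 / sqrt(row$net_counts)
        }
      }
      tld <- ldf[ldf$foil == "TLD", ]
      if (!ok || !nrow(tld) || is.na(tld$gamma_dose_Gy[1])) next
      nf <- solveNormalization(Rmeas, ref@Rsim, locationId = ids[li],
                               relUnc = if (all(is.na(relUnc))) NULL
                                        else ifelse(is.na(relUnc), 0, relUnc),
                               condThreshold = condThreshold,
                               clampNegative = clampNegative)
      bd <- neutronEquivalentDose(nf, ref, pdf$boron_ppm[1], constants)
      hN <- patientHStar(nf, ref, scaled = scaledHStar)
      tot <- totalDoses(bd, hN, tld$gamma_dose_Gy[1], constants)
      tot <- normalizedMetrics(tot, pdf$d95_gy_eq[1], pdf$n_fractions[1],
                               constants, neutronOnly = neutronOnlyEqd2)
      colInfo$tumorEqd2[pi] <- tot$tumorEqd2
      for (a in c("gammaDose", "neutronAbsorbed", "totalAbsorbed",
                  "weightedDose", "neutronHStar", "hStar", "eqd2Weighted",
                  "hStarPerEqd2", "eqd2PerEqd2"))
        A[[a]][li, pi] <- tot[[a]]
      A$boronWeighted[li, pi] <- bd@perComponent["boron"]
      A$nitrogenWeighted[li, pi] <- bd@perComponent["nitrogen"]
      A$hydrogenWeighted[li, pi] <- bd@perComponent["hydrogen"]
      A$nThermal[li, pi] <- nf@N["thermal"]
      A$nEpithermal[li, pi] <- nf@N["epithermal"]
      A$nFast[li, pi] <- nf@N["fast"]
      qa[[length(qa) + 1L]] <- data.frame(
        patient_id = pats[pi], location = ids[li],
        condition_number = nf@conditionNumber,
        flag_negative = nf@flagNegative,
        flag_ill_conditioned = nf@flagIllConditioned,
        n_thermal_sd = nf@nSd["thermal"], n_epithermal_sd = nf@nSd["epithermal"],
        n_fast_sd = nf@nSd["fast"], stringsAsFactors = FALSE)
    }
  }
  rowInfo <- S4Vectors::DataFrame(
    location = ids,
    distance_cm = unname(distanceCm(library)),
    distance_edge_cm = vapply(library@locations,
                              function(l) l@distanceEdgeCm, numeric(1)),
    gamma_primary_fraction = vapply(library@locations,
                                    function(l) l@gammaPrimaryFraction,
                                    numeric(1)))
  qaDf <- if (length(qa)) do.call(rbind, qa) else
    data.frame(patient_id = character(), location = character())
  rownames(qaDf) <- NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = A, rowData = rowInfo,
    colData = S4Vectors::DataFrame(colInfo, row.names = pats),
    metadata = list(qa = qaDf, constants = constants,
                    options = list(clampNegative = clampNegative,
                                   condThreshold = condThreshold,
                                   scaledHStar = scaledHStar,
                                   neutronOnlyEqd2 = neutronOnlyEqd2)))
  new("DoseExperiment", se)
}

#' Export per-measurement results as a flat table
#'
#' One row per patient x location with every dose quantity; the schema of
#' the `results.csv` written by [writeReports()].
#'
#' @param de a [DoseExperiment-class]
#' @return data.frame in long format
#' @export
resultsTable <- function(de) {
  cd <- as.data.frame(SummarizedExperiment::colData(de))
  rd <- as.data.frame(SummarizedExperiment::rowData(de))
  out <- expand.grid(location = rownames(de), patient_id = colnames(de),
                     stringsAsFactors = FALSE)
  out <- merge(out, cd, by = "patient_id", sort = FALSE)
  out <- merge(out, rd[, c("location", "distance_cm", "distance_edge_cm")],
               by = "location", sort = FALSE)
  for (a in .DOSE_ASSAYS)
    out[[a]] <- SummarizedExperiment::assay(de, a)[
      cbind(match(out$location, rownames(de)),
            match(out$patient_id, colnames(de)))]
  out[order(out$patient_id, match(out$location, rownames(de))), ]
}
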