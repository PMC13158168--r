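#' Per-location cohort summary statistics
#'
#' Unweighted mean and sample standard deviation (n-1 denominator) of the
#' gamma, neutron absorbed, total absorbed, biologically weighted and
#' H*(10) quantities at each body location. With `missing = "drop_patient"`
#' (the default, mirroring exclusion of patients with any unavailable
#' measurement point) patients missing any location are removed entirely;
#' with `missing = "per_location"` each location uses all patients measured
#' there, and the excluded count is reported per location.
#'
#' @param de a [DoseExperiment-class]
#' @param missing missing-location policy
#' @return data.frame, one row per location, with n, n_excluded, a
#'   degenerate-sample flag (single patient), and mean/sd columns
#' @export
summarizeCohort <- function(de, missing = c("drop_patient", "per_location")) {
  missing <- match.arg(missing)
  if (ncol(de) == 0L) stop("empty result set")
  quantities <- c("gammaDose", "neutronAbsorbed", "totalAbsorbed",
                  "weightedDose", "hStar", "neutronHStar",
                  "hStarPerEqd2", "eqd2PerEqd2")
  W <- SummarizedExperiment::assay(de, "weightedDose")
  keep <- rep(TRUE, ncol(de))
  if (missing == "drop_patient") {
    keep <- colSums(is.na(W)) == 0L
    if (!any(keep)) stop("no complete patients after drop_patient exclusion")
    if (any(!keep))
      message(sum(!keep), " patient(s) dropped for missing locations")
  }
  out <- data.frame(location = rownames(de),
                    distance_edge_cm =
                      SummarizedExperiment::rowData(de)$distance_edge_cm)
  for (li in seq_len(nrow(de))) {
    vals <- W[li, keep]
    n <- sum(!is.na(vals))
    out$n[li] <- n
    out$n_excluded[li] <- sum(is.na(W[li, keep]))
    out$degenerate[li] <- n == 1L
  }
  if (missing == "per_location" && any(out$n_excluded > 0))
    message("per-location exclusions: ",
            paste(out$location, out$n_excluded, sep = "=", collapse = ", "))
  for (q in quantities) {
    M <- SummarizedExperiment::assay(de, q)[, keep, drop = FALSE]
    out[[paste0(q, "_mean")]] <- rowMeans(M, na.rm = TRUE)
    sds <- apply(M, 1, stats::sd, na.rm = TRUE)
    sds[out$degenerate] <- 0
    out[[paste0(q, "_sd")]] <- sds
  }
  if (any(out$n == 0L)) stop("a location has no measured patients")
  out
}

#' Mean dose-component fractions by treatment-site group
#'
#' For each group x location, the mean fractional contribution of the
#' boron, nitrogen, hydrogen and gamma weighted dose components to the
#' total weighted dose. Fractions are computed per patient and averaged, so
#' every output row sums to 1. Patients with zero total weighted dose at a
#' location are excluded from that cell with a warning.
#'
#' @param de a [DoseExperiment-class]
#' @param by group patients by this colData column ("site_group"), or NULL
#'   for a single overall group
#' @return data.frame with columns group, location, boron, nitrogen,
#'   hydrogen, gamma
#' @export
componentFractions <- function(de, by = "site_group") {
  comp <- lapply(stats::setNames(nm = c("boronWeighted", "nitrogenWeighted",
                                        "hydrogenWeighted", "gammaDose")),
                 function(a) SummarizedExperiment::assay(de, a))
  total <- Reduce(`+`, comp)
  groups <- if (is.null(by)) rep("all", ncol(de)) else
    as.character(SummarizedExperiment::colData(de)[[by]])
  rows <- list()
  for (g in unique(groups)) {
    gi <- which(groups == g)
    for (li in seq_len(nrow(de))) {
      tot <- total[li, gi]
      use <- which(!is.na(tot) & tot > 0)
      if (length(use) < length(which(!is.na(tot))))
        warning("zero-total rows excluded at ", rownames(de)[li])
      if (!length(use)) next
      fr <- vapply(comp, function(M) mean(M[li, gi][use] / tot[use]),
                   numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, location = rownames(de)[li],
        boron = fr[["boronWeighted"]], nitrogen = fr[["nitrogenWeighted"]],
        hydrogen = fr[["hydrogenWeighted"]], gamma = fr[["gammaDose"]],
        n = length(use), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Primary / secondary gamma-ray origin fractions
#'
#' Echoes the per-location primary gamma fraction carried by the reference
#' library (photons from the beam line and room versus photons generated
#' in-patient by hydrogen capture) and its complement, validating that the
#' two sum to 1.
#'
#' @param library a [ReferenceLibrary-class]
#' @return data.frame with columns location, distance_cm, primary, secondary
#' @export
gammaOriginRatios <- function(library) {
  pf <- vapply(library@locations, function(l) l@gammaPrimaryFraction,
               numeric(1))
  if (any(pf < 0 | pf > 1)) stop("primary fraction outside [0, 1]")
  data.frame(location = locationIds(library),
             distance_cm = unname(distanceCm(library)),
             primary = pf, secondary = 1 - pf)
}

#' Dose-versus-distance export for inter-modality comparison
#'
#' One row per location, sorted by distance from the field edge, with the
#' cohort mean and SD of the two EQD2-normalized metrics (total H*(10) per
#' tumor EQD2, and EQD2-converted weighted dose per tumor EQD2) and of the
#' neutron-only H*(10); overlay-ready for TG-158-style comparison plots.
#'
#' @param de a [DoseExperiment-class]
#' @param library a [ReferenceLibrary-class] supplying distances; locations
#'   present in the results but absent from the library raise an error
#' @return data.frame sorted by distance
#' @export
exportDistanceProfile <- function(de, library) {
  ids <- rownames(de)
  libIds <- locationIds(library)
  missing <- setdiff(ids, libIds)
  if (length(missing))
    stop("no configured distance for location(s): ",
         paste(missing, collapse = ", "))
  dist <- vapply(library@locations, function(l) l@distanceEdgeCm, numeric(1))
  dist <- dist[match(ids, libIds)]
  stat <- function(a) {
    M <- SummarizedExperiment::assay(de, a)
    list(mean = rowMeans(M, na.rm = TRUE),
         sd = apply(M, 1, stats::sd, na.rm = TRUE))
  }
  m1 <- stat("hStarPerEqd2"); m2 <- stat("eqd2PerEqd2")
  nh <- stat("neutronHStar")
  out <- data.frame(distance_edge_cm = dist, location = ids,
                    hstar_per_eqd2_mean = m1$mean, hstar_per_eqd2_sd = m1$sd,
                    eqd2_ratio_mean = m2$mean, eqd2_ratio_sd = m2$sd,
                    neutron_hstar_mean = nh$mean, neutron_hstar_sd = nh$sd)
  out[order(out$distance_edge_cm), ]
}

#' Write the full report bundle
#'
#' Writes results.csv (per patient x location), summary.csv, fractions.csv,
#' distance_profile.csv, gamma_origin.csv and qa/<patient>.json under `dir`.
#'
#' @param de a [DoseExperiment-class]
#' @param library a [ReferenceLibrary-class]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
writeReports <- function(de, library, dir) {
  dir.create(file.path(dir, "qa"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(resultsTable(de), file.path(dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(summarizeCohort(de), file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(componentFractions(de), file.path(dir, "fractions.csv"),
                   row.names = FALSE)
  utils::write.csv(exportDistanceProfile(de, library),
                   file.path(dir, "distance_profile.csv"), row.names = FALSE)
  utils::write.csv(gammaOriginRatios(library),
                   file.path(dir, "gamma_origin.csv"), row.names = FALSE)
  qa <- S4Vectors::metadata(de)$qa
  for (pid in unique(qa$patient_id)) {
    jsonlite::write_json(qa[qa$patient_id == pid, ],
                         file.path(dir, "qa", paste0(pid, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}
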