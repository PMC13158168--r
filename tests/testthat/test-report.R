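smallCohort <- function(n = 6, seed = 31) {
  lib <- getTestLib()
  coh <- generateCohort(cohortSpec(nPatients = n, seed = seed), lib)
  list(lib = lib, de = analyzeCohort(coh$measurements, lib), coh = coh)
}

test_that("cohort summary uses sample SD and handles degenerate samples", {
  s <- smallCohort()
  sum6 <- summarizeCohort(s$de)
  W <- SummarizedExperiment::assay(s$de, "weightedDose")
  # two-patient hand formula: mean (a+b)/2, SD |a-b|/sqrt(2)
  de2 <- s$de[, 1:2]
  sum2 <- summarizeCohort(de2)
  a <- W[1, 1]; b <- W[1, 2]
  expect_equal(sum2$weightedDose_mean[1], (a + b) / 2)
  expect_equal(sum2$weightedDose_sd[1], abs(a - b) / sqrt(2))
  # single patient: SD 0 with the degenerate flag
  sum1 <- summarizeCohort(s$de[, 1])
  expect_true(all(sum1$degenerate))
  expect_true(all(sum1$weightedDose_sd == 0))
  expect_error(summarizeCohort(s$de[, 0]), "empty")
  # permutation invariance over patients
  perm <- sample(ncol(s$de))
  expect_equal(summarizeCohort(s$de[, perm])$weightedDose_mean,
               sum6$weightedDose_mean)
})

test_that("missing-location policies: drop patient entirely or per-location", {
  s <- smallCohort()
  m <- s$coh$measurements
  drop <- !(m$patient_id == "P0001" & m$location == "knee")
  de <- analyzeCohort(m[drop, ], s$lib)
  expect_message(sdrop <- summarizeCohort(de, missing = "drop_patient"),
                 "dropped")
  expect_true(all(sdrop$n == ncol(de) - 1L))
  sloc <- summarizeCohort(de, missing = "per_location")
  expect_equal(sloc$n[sloc$location == "knee"], ncol(de) - 1L)
  expect_equal(sloc$n[sloc$location == "neck"], ncol(de))
})

test_that("component fractions sum to 1, respect symmetry and scale invariance", {
  s <- smallCohort()
  fr <- componentFractions(s$de)
  expect_true(all(abs(rowSums(fr[, c("boron", "nitrogen", "hydrogen",
                                     "gamma")]) - 1) < 1e-9))
  fr_all <- componentFractions(s$de, by = NULL)
  expect_equal(nrow(fr_all), nrow(s$de))
  # group sizes sum to the cohort size at each location
  for (loc in unique(fr$location))
    expect_equal(sum(fr$n[fr$location == loc]), ncol(s$de))
  # all-gamma patient: gamma fraction 1; equal components: 0.25 each
  mk <- function(bor, nit, hyd, gam) {
    A <- lapply(stats::setNames(nm = bnctdose:::.DOSE_ASSAYS), function(a)
      matrix(0, 1, 1, dimnames = list("neck", "P1")))
    A$boronWeighted[] <- bor; A$nitrogenWeighted[] <- nit
    A$hydrogenWeighted[] <- hyd; A$gammaDose[] <- gam
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = A,
      rowData = S4Vectors::DataFrame(location = "neck", distance_cm = 15,
                                     distance_edge_cm = 7.5,
                                     gamma_primary_fraction = 0.3),
      colData = S4Vectors::DataFrame(site_group = "oropharyngeal",
                                     row.names = "P1"))
    new("DoseExperiment", se)
  }
  expect_equal(unlist(componentFractions(mk(0, 0, 0, 0.4))[,
                 c("boron", "nitrogen", "hydrogen", "gamma")]),
               c(boron = 0, nitrogen = 0, hydrogen = 0, gamma = 1))
  expect_equal(unname(unlist(componentFractions(mk(1, 1, 1, 1))[,
                 c("boron", "nitrogen", "hydrogen", "gamma")])),
               rep(0.25, 4))
  expect_equal(componentFractions(mk(2, 4, 6, 8))[, -(1:2)],
               componentFractions(mk(1, 2, 3, 4))[, -(1:2)])
})

test_that("gamma origin table round-trips the library and complements to 1", {
  lib <- getTestLib()
  go <- gammaOriginRatios(lib)
  expect_equal(nrow(go), 6)
  expect_equal(go$primary + go$secondary, rep(1, 6))
  expect_equal(go$primary[go$location == "knee"], 0.916)
  expect_equal(go$primary[go$location == "ankle"], 0.272)
  expect_equal(go$primary,
               vapply(lib@locations, primaryFraction, numeric(1)))
})

test_that("distance profile is sorted, complete, and errors on unknown locations", {
  s <- smallCohort()
  prof <- exportDistanceProfile(s$de, s$lib)
  expect_equal(nrow(prof), 6)            # one row per configured location
  expect_true(!is.unsorted(prof$distance_edge_cm, strictly = TRUE))
  # neutron-derived quantity decreases with distance on the synthetic cohort
  expect_true(all(diff(prof$neutron_hstar_mean) < 0))
  renamed <- s$de
  rownames(renamed)[1] <- "elbow"
  expect_error(exportDistanceProfile(renamed, s$lib), "elbow")
  # single location still exports a single row
  one <- exportDistanceProfile(s$de[2, ], s$lib)
  expect_equal(nrow(one), 1)
  expect_equal(one$location, "chest")
})

test_that("weighted dose dominates absorbed dose when all weights exceed 1", {
  s <- smallCohort(n = 8, seed = 13)
  W <- SummarizedExperiment::assay(s$de, "weightedDose")
  A <- SummarizedExperiment::assay(s$de, "totalAbsorbed")
  expect_true(all(W >= A - 1e-12))
})

test_that("report bundle writes the documented artifact set", {
  s <- smallCohort(n = 3, seed = 8)
  dir <- withr::local_tempdir()
  writeReports(s$de, s$lib, dir)
  for (f in c("results.csv", "summary.csv", "fractions.csv",
              "distance_profile.csv", "gamma_origin.csv"))
    expect_true(file.exists(file.path(dir, f)))
  expect_length(list.files(file.path(dir, "qa")), 3)
  res <- utils::read.csv(file.path(dir, "results.csv"))
  expect_equal(nrow(res), 3 * 6)
  expect_true(all(res$totalAbsorbed - (res$gammaDose + res$neutronAbsorbed)
                  < 1e-10))
})
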