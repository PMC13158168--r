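test_that("3x3 solve handles identity, hand-multiplied, and zero cases", {
  I3 <- diag(3) * 5
  nf <- solveNormalization(c(5, 5, 5), I3)
  expect_equal(unname(normFactors(nf)), c(1, 1, 1))
  A <- matrix(c(2, 1, 0, 1, 3, 0, 0, 0, 4), 3, 3)  # columns of the forward map
  nf <- solveNormalization(c(3, 6.5, 1), A)
  expect_equal(unname(normFactors(nf)), c(0.5, 2, 0.25))
  nf <- solveNormalization(c(0, 0, 0), A)
  expect_equal(unname(normFactors(nf)), c(0, 0, 0))
  expect_false(nf@flagNegative)
  expect_error(solveNormalization(c(1, 1, 1), matrix(1, 3, 3)), "singular")
})

test_that("forward-then-unfold recovers factors to machine precision", {
  set.seed(42)
  worst <- 0
  for (i in 1:300) {
    A <- matrix(runif(9, 0.5, 2), 3, 3) + 3 * diag(3)
    N0 <- runif(3, 0.1, 3)
    nf <- solveNormalization(as.numeric(A %*% N0), A)
    worst <- max(worst, max(abs(normFactors(nf) / N0 - 1)))
  }
  expect_lt(worst, 1e-10)
})

test_that("negative components are preserved and flagged; clamping is opt-in", {
  A <- diag(3)
  nf <- solveNormalization(c(1, -0.2, 1), A)
  expect_true(nf@flagNegative)
  expect_equal(unname(normFactors(nf))[2], -0.2)
  nf2 <- solveNormalization(c(1, -0.2, 1), A, clampNegative = TRUE)
  expect_true(nf2@flagNegative)
  expect_equal(unname(normFactors(nf2))[2], 0)
})

test_that("ill-conditioning warns, flags, and still solves; diagnostics scale-invariant", {
  A <- matrix(c(1, 1, 0, 1, 1 + 1e-8, 0, 0, 0, 1), 3, 3)
  expect_warning(nf <- solveNormalization(c(2, 2, 1), A, condThreshold = 1e6),
                 "ill-conditioned")
  expect_true(nf@flagIllConditioned)
  expect_true(all(is.finite(normFactors(nf))))
  # row scaling (foil sensitivity magnitude) does not change the diagnostic
  B <- handReference()@Rsim
  expect_equal(responseCondition(B), responseCondition(B * c(1e-10, 1e-12, 1e-17)),
               tolerance = 1e-6)
})

test_that("uncertainty propagation follows first-order covariance", {
  A <- diag(c(2, 4, 5))
  nf <- solveNormalization(c(2, 4, 5), A, relUnc = c(0.1, 0.05, 0.2))
  # diagonal system: sd(N_i) = relUnc_i * Rmeas_i / A_ii
  expect_equal(unname(nf@nSd), c(0.1 * 2 / 2, 0.05 * 4 / 4, 0.2 * 5 / 5))
})

test_that("dose model arithmetic matches the hand-evaluated weighting", {
  ref <- handReference()      # thermal components (0.1, 0.05, 0.02) Gy
  bc <- biologyConstants()
  bd <- neutronEquivalentDose(unitFactors(), ref, boronPpm = 25, bc)
  expect_equal(bd@total, 2.5 * 0.1 + 2.9 * 0.05 + 2.4 * 0.02)  # 0.443
  expect_equal(bd@total, 0.443, tolerance = 1e-12)
  # doubling blood boron doubles the boron component only
  bd50 <- neutronEquivalentDose(unitFactors(), ref, boronPpm = 50, bc)
  expect_equal(bd50@perComponent[["boron"]], 2 * bd@perComponent[["boron"]])
  expect_equal(bd50@perComponent[["nitrogen"]], bd@perComponent[["nitrogen"]])
  expect_equal(bd50@perComponent[["hydrogen"]], bd@perComponent[["hydrogen"]])
  # zero factors -> zero dose
  bd0 <- neutronEquivalentDose(unitFactors(c(0, 0, 0)), ref, 25, bc)
  expect_equal(bd0@total, 0)
})

test_that("region and component partitions agree and scale linearly in N", {
  set.seed(7)
  D <- matrix(runif(9, 0, 0.2), 3, 3,
              dimnames = list(c("boron", "nitrogen", "hydrogen"), REGIONS))
  ref <- handReference(Dref = D)
  bc <- biologyConstants()
  for (i in 1:20) {
    N <- runif(3, 0, 2)
    bd <- neutronEquivalentDose(unitFactors(N), ref, 30, bc)
    expect_equal(sum(bd@perRegion), bd@total, tolerance = 1e-10)
    expect_equal(sum(bd@perComponent), bd@total, tolerance = 1e-10)
    bd2 <- neutronEquivalentDose(unitFactors(2 * N), ref, 30, bc)
    expect_equal(bd2@total, 2 * bd@total, tolerance = 1e-12)
  }
})

test_that("patient H*(10) is the factor-weighted sum of per-region references", {
  ref <- handReference(Href = c(3, 2, 1))
  expect_equal(patientHStar(unitFactors(), ref), 6)
  expect_equal(patientHStar(unitFactors(c(2, 0, 0)), ref), 6 - 6 + 2 * 3)
  N <- c(0.8, 1.3, 0.4)
  expect_equal(patientHStar(unitFactors(N), ref),
               sum(N * c(3, 2, 1)), tolerance = 1e-15)
  # unscaled mode ignores the factors
  expect_equal(patientHStar(unitFactors(N), ref, scaled = FALSE), 6)
})
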