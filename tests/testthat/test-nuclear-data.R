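test_that("energy regions partition (1e-20, 30] MeV with upper-inclusive cuts", {
  g <- defaultEnergyGrid()
  expect_identical(regionOfEnergy(1e-8, g), "thermal")
  expect_identical(regionOfEnergy(5.3e-7, g), "thermal")   # cut is inclusive
  expect_identical(regionOfEnergy(5.31e-7, g), "epithermal")
  expect_identical(regionOfEnergy(1e-2, g), "epithermal")
  expect_identical(regionOfEnergy(1.0, g), "fast")
  expect_identical(regionOfEnergy(30, g), "fast")
  expect_error(regionOfEnergy(1e-20, g), "domain")
  expect_error(regionOfEnergy(31, g), "domain")
  # every fine group maps to exactly one region; all regions populated
  expect_length(groupRegions(g), nGroups(g))
  expect_setequal(unique(groupRegions(g)), c("thermal", "epithermal", "fast"))
  # region cuts land exactly on grid edges
  expect_true(all(c(5.3e-7, 1e-2) %in% gridEdges(g)))
  expect_identical(regionOfEnergy(gridMidpoints(g), g), groupRegions(g))
})

test_that("H*(10) interpolation is log-log, exact at nodes, and bounded", {
  co <- ambientDoseCoefficients()
  # identity at every tabulated node
  expect_equal(interpolateHStar(co$energy_MeV, co), co$h_star)
  # geometric-mean oracle: log-log value at sqrt(x1 x2) is sqrt(y1 y2)
  for (i in c(5L, 20L, 40L)) {
    xg <- sqrt(co$energy_MeV[i] * co$energy_MeV[i + 1])
    expect_equal(interpolateHStar(xg, co),
                 sqrt(co$h_star[i] * co$h_star[i + 1]), tolerance = 1e-12)
  }
  # monotone between any two tabulated points
  for (i in seq_len(nrow(co) - 1L)) {
    xs <- exp(seq(log(co$energy_MeV[i]), log(co$energy_MeV[i + 1]),
                  length.out = 5))
    xs <- pmin(pmax(xs, co$energy_MeV[i]), co$energy_MeV[i + 1])
    ys <- interpolateHStar(xs, co)
    expect_true(all(diff(ys) >= -1e-12 * abs(ys[-1])) ||
                  all(diff(ys) <= 1e-12 * abs(ys[-1])))
  }
  expect_error(interpolateHStar(1e-25, co), "outside")
  expect_error(interpolateHStar(50, co), "outside")
})

test_that("group averaging: constant identity, 1/v closed form, threshold zeros", {
  g <- coarseGrid()
  # constant pointwise sigma -> same constant in every group
  pw <- data.frame(energy_MeV = c(1e-20, 1e-10, 1e-3, 30), sigma = 7)
  expect_equal(groupAverageSigma("Au", g, pw)@sigma, rep(7, nGroups(g)))
  # 1/v: lethargy-weighted mean of c E^-1/2 over [a,b] is
  # 2c (a^-1/2 - b^-1/2) / ln(b/a)
  E <- 10^seq(-20, log10(30), length.out = 40)
  E[1] <- 1e-20; E[40] <- 30
  c0 <- 98.65 * sqrt(2.53e-8)
  pw <- data.frame(energy_MeV = E, sigma = c0 / sqrt(E))
  got <- groupAverageSigma("Au", g, pw)@sigma
  edges <- gridEdges(g)
  a <- edges[-length(edges)]; b <- edges[-1]
  expected <- 2 * c0 * (1 / sqrt(a) - 1 / sqrt(b)) / log(b / a)
  expect_equal(got, expected, tolerance = 1e-10)
  # Al(n,alpha): exactly zero for every group entirely below 3.4 MeV
  al <- groupAverageSigma("Al", g)
  below <- b <= 3.4
  expect_identical(al@sigma[below], rep(0, sum(below)))
  expect_gt(al@sigma[!below][sum(!below)], 0)
  # coverage guard
  short <- data.frame(energy_MeV = c(1e-5, 30), sigma = c(1, 1))
  expect_error(groupAverageSigma("Au", g, short), "cover")
})

test_that("shipped cross sections are nonnegative with Au above Mn at thermal energies", {
  g <- defaultEnergyGrid()
  au <- groupAverageSigma("Au", g)@sigma
  mn <- groupAverageSigma("Mn", g)@sigma
  al <- groupAverageSigma("Al", g)@sigma
  expect_true(all(au >= 0) && all(mn >= 0) && all(al >= 0))
  th <- groupRegions(g) == "thermal"
  expect_true(all(au[th] > mn[th]))
})

test_that("constants and foil specs carry the documented values and guards", {
  fs <- foilSpecs()
  lines <- vapply(fs, function(s) s$gamma_line_keV, numeric(1))
  expect_equal(unname(lines[c("Au", "Mn", "Al")]), c(412, 847, 1369))
  expect_true(all(vapply(fs, function(s) s$half_life_s, numeric(1)) > 0))
  expect_equal(fs$Mn$element_mass_fraction, 0.13)
  bc <- biologyConstants()
  expect_equal(bc$CBE_skin, 2.5)
  expect_equal(bc$RBE_N, 2.9)
  expect_equal(bc$RBE_H, 2.4)
  expect_equal(bc$tumor_blood_ratio, 2.5)
  expect_equal(bc$CBE_tumor, 3.8)
  expect_equal(bc$gamma_Sv_per_Gy, 1)
  w <- tissueComposition()
  expect_equal(sum(w), 1, tolerance = 1e-3)
})
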