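table4 <- data.frame(
  stain = c(100, 200, 300, 400, 500, 600),
  d_constant = c(62.74, 117.90, 170.51, 221.54, 271.42, 320.40),
  d_binned = c(58.82, 111.11, 157.89, 200.00, 238.10, 285.71),
  pct = c(6.25, 5.76, 7.40, 9.72, 12.28, 10.83))

test_that("analytic spread-factor comparison reproduces the reference grid", {
  rep <- runSpreadFactorComparison(table4$stain, mode = "analytic")
  expect_equal(round(rep$table$d_constant_um, 2), table4$d_constant)
  expect_equal(round(rep$table$d_binned_um, 2), table4$d_binned)
  expect_equal(rep$table$pct_difference, table4$pct)
  expect_true(all(rep$table$vol_constant_uL > rep$table$vol_binned_uL))
})

test_that("single-stain report is consistent with the unit operations", {
  rep <- runSpreadFactorComparison(350, mode = "analytic")
  expect_equal(nrow(rep$table), 1)
  dc <- dropletDiameter(constantSpreadFactor(), area = pi * 175^2)
  db <- dropletDiameter(binnedSpreadFactor(), stainDiameter = 350)
  expect_equal(rep$table$pct_difference,
               round(percentDifference(dc, db), 2))
  expect_equal(rep$table$vol_constant_uL, dropletVolume(dc))
})

test_that("constant model yields higher mean volume on skewed fields", {
  d <- sampleStainDiameters(33, c(95.5, 1438), seed = 12)
  rep <- runSpreadFactorComparison(d, mode = "analytic", seed = 12)
  expect_gt(rep$summary$mean_vol_constant_uL,
            rep$summary$mean_vol_binned_uL)
  expect_gt(rep$summary$pct_mean_vol_higher, 0)
  ci <- rep$summary$pct_mean_vol_higher_ci95
  expect_gt(ci[1], 0)   # bootstrap CI excludes zero
})

test_that("analytic and rasterized comparisons converge at high dpi", {
  d <- c(200, 400, 800)
  ana <- runSpreadFactorComparison(d, mode = "analytic")
  ras <- runSpreadFactorComparison(d, mode = "rasterized", dpi = 2400)
  relDiff <- abs(ras$table$d_constant_um - ana$table$d_constant_um) /
    ana$table$d_constant_um
  expect_true(all(relDiff < 0.01))
})

test_that("touching-droplet arithmetic: closed form and additivity", {
  rt <- runTouchingTest(c(150, 400, 900), mode = "analytic")
  expect_equal(rt$table$overestimation_pct,
               rep(100 * (2^0.365 - 1), 3))
  # separated deposition is exactly twice a single stain
  m <- constantSpreadFactor()
  single <- dropletVolume(dropletDiameter(m, area = pi * 200^2))
  expect_equal(rt$table$vol_separated_uL[rt$table$stain_diameter_um ==
                                           400], 2 * single)
})

test_that("rasterized touching pairs always merge and overestimate", {
  d <- exp(seq(log(95.5), log(1438), length.out = 8))
  rt <- runTouchingTest(d, mode = "rasterized", dpi = 600, seed = 2)
  expect_true(all(rt$table$n_components_touching == 1))
  expect_true(all(rt$table$n_components_separated == 2))
  expect_true(all(rt$table$overestimation_pct > 0))
  expect_gt(rt$summary$mean_overestimation_pct, 0)
})

test_that("experiment reports are bit-reproducible from config + seed", {
  d <- sampleStainDiameters(10, seed = 6)
  a <- runSpreadFactorComparison(d, mode = "rasterized", dpi = 600,
                                 seed = 3)
  b <- runSpreadFactorComparison(d, mode = "rasterized", dpi = 600,
                                 seed = 3)
  expect_identical(a$table, b$table)
  expect_identical(a$summary, b$summary)
})

test_that("method comparison reproduces the headline calibration", {
  # arms fixed at the printed means: cf and corrected mean follow
  leaf <- rep(0.039, 10)
  cards <- data.frame(coverage_pct = rep(10, 8),
                      deposition_uL_per_cm2 = rep(0.24 / 0.18, 8))
  mc <- compareMethods(leaf, cards, concentration = 0.18)
  expect_equal(correctionFactor(mc$correction), 0.1625)
  expect_equal(mc$corrected_summary$mean, 0.039)
  expect_equal(mc$ratio_uncorrected, 0.24 / 0.039)

  # equal arms: correction is the identity
  cardsEq <- data.frame(coverage_pct = rep(5, 6),
                        deposition_uL_per_cm2 = rep(0.039 / 0.18, 6))
  mcEq <- compareMethods(rep(0.039, 6), cardsEq, 0.18)
  expect_equal(correctionFactor(mcEq$correction), 1)
  expect_equal(mcEq$corrected_summary$mean, mcEq$leaf_summary$mean)
})

test_that("method comparison recovers a built-in factor and excludes cards", {
  sim <- simulatePairedResidues(0.16, nLeaf = 120, nWsp = 100, seed = 9)
  cards <- data.frame(coverage_pct = c(rep(12, 100), rep(60, 10)),
                      deposition_uL_per_cm2 =
                        c(sim$wsp / 0.18, rep(9, 10)))
  mc <- compareMethods(sim$leaf, cards, concentration = 0.18)
  expect_equal(mc$exclusion$n_excluded, 10)
  expect_lt(abs(correctionFactor(mc$correction) - 0.16) / 0.16, 0.05)
  expect_error(compareMethods(sim$leaf,
                              data.frame(coverage_pct = 50,
                                         deposition_uL_per_cm2 = 1),
                              0.18), "no WSP cards remain")
})
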