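test_that("equivalent-circle diameter inverts circle area", {
  expect_equal(stainDiameterFromArea(pi * 50^2), 100)
  expect_equal(stainDiameterFromArea(0), 0)
  expect_equal(stainDiameterFromArea(7853.98), 100, tolerance = 1e-5)
  # round trip over a diameter grid
  d <- seq(10, 2000, by = 37)
  expect_equal(stainDiameterFromArea(pi * (d / 2)^2), d)
  expect_error(stainDiameterFromArea(-1), "non-negative")
})

test_that("constant power-law model reproduces the reference stain sizes", {
  m <- constantSpreadFactor()
  expect_equal(round(dropletDiameter(m, area = pi * 50^2), 2), 62.74)
  expect_equal(round(dropletDiameter(m, area = pi * 100^2), 2), 117.90)
  expect_equal(dropletDiameter(m, area = 0), 0)
  # strictly increasing in area
  a <- seq(100, 1e6, length.out = 200)
  expect_true(all(diff(dropletDiameter(m, area = a)) > 0))
  expect_error(dropletDiameter(m, area = -5), "non-negative")
  # dispatch rejects things that are not models
  expect_error(dropletDiameter(list(kind = "constant"), area = 1))
})

test_that("binned model divides by the bin's spread factor", {
  b <- binnedSpreadFactor()
  expect_equal(round(dropletDiameter(b, stainDiameter = 100), 2), 58.82)
  expect_equal(round(dropletDiameter(b, stainDiameter = 500), 2), 238.10)
  expect_equal(dropletDiameter(b, stainDiameter = 450), 450 / 2.1)
  # half-open bins: 100 um belongs to the first bin, 100.01 to the second
  expect_equal(spreadFactorAt(b, 100), 1.7)
  expect_equal(spreadFactorAt(b, 100.01), 1.8)
  expect_equal(spreadFactorAt(b, c(1, 300, 400.0001)), c(1.7, 1.9, 2.1))
  # beyond the table the factor clamps to the plateau value
  expect_equal(spreadFactorAt(b, 5000), 2.1)
  expect_error(spreadFactorAt(b, 0), "positive")
})

test_that("model construction enforces the declared invariants", {
  expect_error(constantSpreadFactor(sf = -1), "positive")
  expect_error(constantSpreadFactor(exponent = 1.2), "in \\(0, 1\\)")
  expect_error(binnedSpreadFactor(upper = c(100, 90),
                                  factors = c(1.7, 1.8)), "increasing")
  expect_error(binnedSpreadFactor(upper = c(100, 200),
                                  factors = c(0.5, 1.8)), ">= 1")
})

test_that("droplet volume is the sphere volume in microlitres", {
  expect_equal(dropletVolume(0), 0)
  expect_equal(dropletVolume(100), (pi / 6) * 1e6 * 1e-9)
  expect_equal(dropletVolume(1000), 0.5236, tolerance = 1e-4)
  # cubic scaling: x1000 in volume for x10 in diameter
  expect_equal(dropletVolume(1000) / dropletVolume(100), 1000)
  d <- seq(1, 1500, by = 13)
  expect_true(all(diff(dropletVolume(d)) > 0))
  expect_error(dropletVolume(-1), "non-negative")
})

test_that("constant model exceeds binned model across the tabulated range", {
  m <- constantSpreadFactor(); b <- binnedSpreadFactor()
  ds <- seq(100, 600, by = 2.5)
  dc <- dropletDiameter(m, stainDiameter = ds)
  db <- dropletDiameter(b, stainDiameter = ds)
  expect_true(all(dc > db))
  expect_true(all(percentDifference(dc, db) > 0))
})

test_that("percent difference matches the reference table arithmetic", {
  expect_equal(round(percentDifference(62.74, 58.82), 2), 6.25)
  expect_equal(round(percentDifference(271.42, 238.10), 2), 12.28)
  expect_equal(percentDifference(50, 50), 0)
  expect_error(percentDifference(0, 10), "positive")
  expect_error(percentDifference(10, 0), "positive")
})

test_that("card metrics: zero, saturation and composed deposition", {
  m <- constantSpreadFactor()
  emptyStains <- data.frame(area_um2 = numeric(0),
                            stain_diameter_um = numeric(0))
  z <- cardMetrics(emptyStains, 2, 0, 1000, m)
  expect_equal(coverage(z), 0)
  expect_equal(dropletDensity(z), 0)
  expect_equal(deposition(z), 0)
  expect_false(highCoverage(z))

  one <- data.frame(area_um2 = 1e6, stain_diameter_um =
                      stainDiameterFromArea(1e6))
  full <- cardMetrics(one, 0.5, 1000, 1000, m)
  expect_equal(coverage(full), 100)
  expect_equal(dropletDensity(full), 1 / 0.5)
  expect_true(highCoverage(full))

  st <- data.frame(area_um2 = pi * 50^2, stain_diameter_um = 100)
  cm <- cardMetrics(st, 1, 5, 1e4, m)
  expect_equal(deposition(cm),
               dropletVolume(dropletDiameter(m, area = pi * 50^2)) / 1)
})

test_that("deposition is additive over disjoint stain sets", {
  m <- constantSpreadFactor()
  s1 <- data.frame(area_um2 = c(1e4, 3e4),
                   stain_diameter_um = stainDiameterFromArea(c(1e4, 3e4)))
  s2 <- data.frame(area_um2 = c(5e4, 2e5),
                   stain_diameter_um = stainDiameterFromArea(c(5e4, 2e5)))
  d1 <- deposition(cardMetrics(s1, 1, 10, 100, m))
  d2 <- deposition(cardMetrics(s2, 1, 20, 100, m))
  dU <- deposition(cardMetrics(rbind(s1, s2), 1, 30, 100, m))
  expect_equal(dU, d1 + d2)
})

test_that("merging two equal stains inflates volume by 2^(3b-1) - 1", {
  m <- constantSpreadFactor()
  for (a in c(1e3, 5e4, 2e6)) {
    sep <- 2 * dropletVolume(dropletDiameter(m, area = a))
    mer <- dropletVolume(dropletDiameter(m, area = 2 * a))
    expect_equal(mer / sep - 1, 2^(3 * 0.455 - 1) - 1)
  }
  # brute-force value of the exponent identity
  expect_equal(2^(3 * 0.455 - 1) - 1, 0.2878816, tolerance = 1e-6)
})

test_that("card summary table flattens metrics with residue when present", {
  m <- constantSpreadFactor()
  st <- data.frame(area_um2 = pi * 50^2, stain_diameter_um = 100)
  cm <- cardMetrics(st, 1, 5, 1e4, m)
  tab <- cardSummaryTable(list(cm, cm), cardIds = c("a", "b"))
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("card_id", "coverage_pct", "density_per_cm2",
                      "deposition_uL_per_cm2", "n_stains",
                      "high_coverage_flag"))
})
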