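test_that("rasterization follows the pixel-centre rule", {
  pitch <- 25400 / 600
  # a circle of one pixel pitch centred on a pixel centre marks 1 pixel
  card <- rasterizeCircle(blankCard(11, 11, dpi = 600), 5, 5, pitch)
  expect_equal(sum(cardPixels(card) == 0), 1)
  expect_equal(which(cardPixels(card) == 0), 5 * 11 + 6)  # (x=5, y=5)

  # sub-3-pixel stain: count agrees with the brute-force oracle
  card <- rasterizeCircle(blankCard(12, 12, dpi = 600), 5, 5, 95.5)
  n <- sum(cardPixels(card) == 0)
  expect_equal(n, oraclePixelCount(5, 5, 95.5, 600, 12, 12))
  expect_true(n >= 1 && n <= 5)

  # large stain: measured equivalent-circle diameter within 3%
  card <- rasterizeCircle(blankCard(60, 60, dpi = 600), 30, 30, 1438)
  st <- extractStains(binarize(card), 600)
  expect_lt(abs(st$stain_diameter_um - 1438) / 1438, 0.03)

  expect_error(rasterizeCircle(blankCard(10, 10, dpi = 600), 5, 5, 1438),
               "does not fit")
})

test_that("measured diameter converges to truth as dpi increases", {
  for (d in c(200, 500, 1000)) {
    pitch <- 25400 / 2400
    side <- ceiling(d / pitch) + 10
    mid <- (side - 1) / 2
    card <- rasterizeCircle(blankCard(side, side, dpi = 2400), mid, mid, d)
    st <- extractStains(binarize(card), 2400)
    expect_lt(abs(st$stain_diameter_um - d) / d, 0.01)
  }
})

test_that("tangent pairs merge into one component, separated pairs stay two", {
  for (d in c(95.5, 200, 500, 1438)) {
    pitch <- 25400 / 600
    w <- ceiling(2 * d / pitch) + 16
    h <- ceiling(d / pitch) + 12
    tou <- generateTouchingPair(d, w, h, dpi = 600, touching = TRUE)
    sep <- generateTouchingPair(d, w, h, dpi = 600, touching = FALSE)
    stT <- extractStains(binarize(tou$card), 600)
    stS <- extractStains(binarize(sep$card), 600)
    expect_equal(nrow(stT), 1)
    expect_equal(nrow(stS), 2)
    # merged area equals the union the oracle counts
    expect_equal(stT$pixel_count,
                 sum(oracleCirclePixels(tou$centers, c(d, d), 600, w, h)))
    # merged extent is ~2d x d: roughly double a single stain's area
    expect_gt(stT$pixel_count, 1.5 * max(stS$pixel_count))
  }
})

test_that("generated cards carry exact ground truth", {
  # empty diameter list -> blank card
  gen <- generateCard(numeric(0), 50, 50, dpi = 600, seed = 1)
  expect_equal(nrow(gen$truth), 0)
  expect_true(all(cardPixels(gen$card) == 255))

  # a field-like card: 33 log-uniform stains are all recovered
  d <- sampleStainDiameters(33, c(95.5, 1438), seed = 7)
  gen <- generateCard(d, 900, 700, dpi = 600, seed = 7)
  mask <- binarize(gen$card)
  st <- extractStains(mask, 600)
  expect_equal(nrow(st), 33)
  # conservation: segmented pixels equal rasterized pixels
  expect_equal(sum(st$pixel_count), sum(mask))
  expect_equal(sum(st$pixel_count), sum(gen$truth$pixel_count))

  # placement is reproducible from the seed
  gen2 <- generateCard(d, 900, 700, dpi = 600, seed = 7)
  expect_identical(gen$truth, gen2$truth)
  expect_identical(cardPixels(gen$card), cardPixels(gen2$card))

  expect_error(generateCard(rep(1300, 50), 120, 120, dpi = 600, seed = 1),
               "larger card")
})

test_that("binarization is exact on noiseless cards and robust to noise", {
  gen <- generateCard(c(300, 500, 800, 400), 200, 150, dpi = 600,
                      seed = 11)
  truthMask <- cardPixels(gen$card) == 0
  expect_identical(binarize(gen$card), truthMask)

  # all-background card: empty mask (uniform image falls back with a
  # warning and the fixed threshold keeps white as background)
  blank <- blankCard(30, 30, dpi = 600)
  expect_warning(m <- binarize(blank), "uniform image")
  expect_false(any(m))

  # Gaussian intensity noise sigma = 10: < 1% pixel disagreement
  set.seed(42)
  px <- cardPixels(gen$card) + rnorm(length(cardPixels(gen$card)), 0, 10)
  noisy <- wspCard(pmin(pmax(px, 0), 255), 600)
  expect_lt(mean(binarize(noisy) != truthMask), 0.01)
})

test_that("fixed-threshold mode uses the configured cutoff", {
  card <- wspCard(matrix(c(10, 100, 200, 250), 2, 2), 600)
  cfgLow <- segmentationConfig("fixed", fixedThreshold = 50)
  cfgHigh <- segmentationConfig("fixed", fixedThreshold = 210)
  expect_equal(sum(binarize(card, cfgLow)), 1)
  expect_equal(sum(binarize(card, cfgHigh)), 3)
})

test_that("component labelling respects connectivity and minPixels", {
  # two pixels touching only diagonally
  mask <- matrix(FALSE, 4, 4)
  mask[1, 1] <- TRUE; mask[2, 2] <- TRUE
  st8 <- extractStains(mask, 600, segmentationConfig(connectivity = 8))
  st4 <- extractStains(mask, 600, segmentationConfig(connectivity = 4))
  expect_equal(nrow(st8), 1)
  expect_equal(nrow(st4), 2)

  # minPixels filter drops small components (4-connectivity keeps the
  # diagonal pixels as two singletons, both below the floor)
  cfg <- segmentationConfig(connectivity = 4, minPixels = 2)
  stMin <- extractStains(mask, 600, cfg)
  expect_equal(nrow(stMin), 0)

  # pixel count to physical area conversion uses the pitch squared
  pitch <- 25400 / 600
  expect_equal(st8$area_um2, 2 * pitch^2)
  expect_equal(st8$stain_diameter_um, 2 * sqrt(2 * pitch^2 / pi))
})

test_that("4-connected labelling agrees with EBImage::bwlabel", {
  set.seed(99)
  for (i in 1:5) {
    mask <- matrix(runif(30 * 40) < 0.35, 30, 40)
    ours <- extractStains(mask, 600, segmentationConfig(connectivity = 4))
    ref <- EBImage::bwlabel(t(mask) * 1)
    expect_equal(nrow(ours), max(ref))
    expect_equal(sum(ours$pixel_count), sum(mask))
    refCounts <- sort(tabulate(as.integer(ref[ref > 0])))
    expect_equal(sort(ours$pixel_count), refCounts)
  }
})

test_that("n disjoint discs yield n stain records with oracle-exact areas", {
  d <- c(150, 300, 450, 700, 1000)
  gen <- generateCard(d, 300, 260, dpi = 600, seed = 5)
  st <- extractStains(binarize(gen$card), 600)
  expect_equal(nrow(st), length(d))
  # every component's pixel count matches the generator's ground truth
  expect_equal(sort(st$pixel_count), sort(gen$truth$pixel_count))
})

test_that("card geometry accessors follow the dpi", {
  card <- blankCard(200, 100, dpi = 600)
  expect_equal(pixelPitch(card), 25400 / 600)
  expect_equal(cardArea(card), 200 * 100 * (25400 / 600)^2 * 1e-8)
  expect_error(wspCard(matrix(0, 2, 2), dpi = 0), "positive")
  expect_error(wspCard(matrix(300, 2, 2), dpi = 600), "\\[0, 255\\]")
})

test_that("card images survive a PNG write/read round trip", {
  gen <- generateCard(c(400, 800), 80, 60, dpi = 600, seed = 2)
  path <- tempfile(fileext = ".png")
  writeCardImage(gen$card, path)
  back <- readCardImage(path, dpi = 600)
  expect_equal(dim(cardPixels(back)), dim(cardPixels(gen$card)))
  expect_identical(binarize(back), binarize(gen$card))
  expect_error(readCardImage(tempfile(fileext = ".bmp"), 600), "not found")
  bad <- tempfile(fileext = ".bmp"); file.create(bad)
  expect_error(readCardImage(bad, 600), "unsupported image format")
})
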