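test_that("background subtraction removes constants and preserves peaks", {
  ## constant image -> all zero
  flat <- IntensityImage(matrix(37, 40, 40), bitDepth = 8L)
  expect_true(all(pixels(subtractBackground(flat, 10)) == 0))
  ## single bright pixel survives a large-radius opening almost intact
  spike <- matrix(0, 120, 120); spike[60, 60] <- 200
  out <- subtractBackground(IntensityImage(spike, bitDepth = 8L), 50)
  expect_gte(pixels(out)[60, 60], 0.95 * 200)
  ## oracle: direct grayscale opening of the same raster ([0,1] domain)
  bg <- as.matrix(EBImage::opening(spike / 255,
                                   EBImage::makeBrush(101, "disc"))) * 255
  expect_equal(pixels(out), pmax(spike - bg, 0), ignore_attr = TRUE)
  ## shift invariance: adding a constant changes nothing
  base <- matrix(sample(0:100, 50 * 50, replace = TRUE), 50, 50)
  a <- subtractBackground(IntensityImage(base, bitDepth = 8L), 5)
  b <- subtractBackground(IntensityImage(base + 100, bitDepth = 8L), 5)
  expect_equal(pixels(a), pixels(b))
  expect_error(subtractBackground(flat, 0), "InvalidRadius")
})

test_that("thresholding separates classes and handles degenerate input", {
  ## perfectly separable two-valued image
  m <- matrix(10, 20, 20); m[5:10, 5:10] <- 240
  res <- autoThreshold(IntensityImage(m, bitDepth = 8L))
  expect_true(res$threshold >= 10 && res$threshold <= 239)
  expect_equal(res$binary, m == 240, ignore_attr = TRUE)
  ## two-Gaussian mixture (means 50 and 200, sd 10, equal counts): the
  ## between-class variance is constant across the empty gap between the
  ## populations, and ties break toward the lower threshold, so otsu sits
  ## at the gap's lower edge and separates the two populations cleanly
  set.seed(42)
  v <- round(c(rnorm(5000, 50, 10), rnorm(5000, 200, 10)))
  v <- pmin(pmax(v, 0), 255)
  mix <- matrix(v, 100, 100)
  resm <- autoThreshold(IntensityImage(mix, bitDepth = 8L))
  expect_gte(resm$threshold, max(v[1:5000]) - 1)
  expect_lte(resm$threshold, 160)
  expect_true(all(resm$binary[matrix(v, 100, 100) >= 170]))
  expect_false(any(resm$binary[matrix(v, 100, 100) <= 80]))
  ## and equals the exhaustive between-class-variance oracle
  expect_equal(resm$threshold, bruteOtsu(as.integer(mix), 256))
  ## constant image: empty foreground with a warning, not an error
  expect_warning(resc <- autoThreshold(IntensityImage(matrix(7, 5, 5),
                                                      bitDepth = 8L)),
                 "DegenerateHistogram")
  expect_false(any(resc$binary))
  ## strictly-greater comparison: ties at the threshold are background
  resf <- autoThreshold(matrix(c(5, 10, 20), 1, 3), method = "fixed",
                        fixedThreshold = 10)
  expect_equal(as.vector(resf$binary), c(FALSE, FALSE, TRUE))
  ## triangle method returns a valid threshold on a skewed histogram
  skew <- matrix(pmin(round(rexp(2500, 1 / 20)), 255), 50, 50)
  skew[1:5, 1:5] <- 250
  rest <- autoThreshold(IntensityImage(skew, bitDepth = 8L),
                        method = "triangle")
  expect_true(rest$threshold > 0 && rest$threshold < 255)
})

test_that("otsu equals exhaustive variance maximization on random images", {
  set.seed(7)
  for (i in 1:20) {
    m <- matrix(sample(0:255, 400, replace = TRUE,
                       prob = runif(256)^2), 20, 20)
    if (min(m) == max(m)) next
    res <- autoThreshold(IntensityImage(m, bitDepth = 8L))
    expect_identical(res$threshold, as.numeric(bruteOtsu(as.integer(m), 256)))
  }
})

test_that("watershed splits touching discs at the bisector and never merges", {
  ## genuinely overlapping discs: cut within +/-2 px of the perpendicular
  ## bisector (analytic distance-map maxima lie at the two centers)
  bin <- makeDiscs(rbind(c(40, 30, 15), c(40, 50, 15)), 80, 80)
  lm <- watershedSplit(bin)
  expect_equal(nLabels(lm), 2L)
  l <- labelMatrix(lm)
  cut1 <- max(col(l)[l == labelMatrix(lm)[40, 30]])
  cut2 <- min(col(l)[l == labelMatrix(lm)[40, 50]])
  expect_lte(abs(cut1 - 40), 2)
  expect_lte(abs(cut2 - 40), 2)
  ## a single disc is left whole
  disc <- makeDisc(20)
  lmd <- watershedSplit(disc)
  expect_equal(nLabels(lmd), 1L)
  ## pixel union unchanged except watershed-line pixels (here: none removed)
  expect_equal(sum(labelMatrix(lmd) > 0), sum(disc))
  ## two already-separate blobs keep their exact pixel sets
  sep <- matrix(0, 60, 60); sep[5:15, 5:15] <- 1; sep[40:50, 35:55] <- 1
  lms <- watershedSplit(sep)
  expect_equal(nLabels(lms), 2L)
  expect_equal(labelMatrix(lms) > 0, sep == 1, ignore_attr = TRUE)
  ## empty input
  expect_equal(nLabels(watershedSplit(matrix(0, 10, 10))), 0L)
})

test_that("watershed count never drops below plain component count", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    spec <- cbind(sample(10:70, k, replace = TRUE),
                  sample(10:70, k, replace = TRUE),
                  sample(4:12, k, replace = TRUE))
    bin <- makeDiscs(spec, 80, 80)
    ncc <- max(labelComponents(bin, 8L))
    nws <- nLabels(watershedSplit(bin))
    expect_gte(nws, ncc)
    ## labeled pixels are a subset of the input foreground
    expect_true(all(bin[labelMatrix(watershedSplit(bin)) > 0] == 1))
  }
})

test_that("component labeling respects connectivity and scan order", {
  m <- matrix(0, 4, 4); m[1, 1] <- 1; m[2, 2] <- 1
  expect_equal(max(labelComponents(m, 4L)), 2L)
  expect_equal(max(labelComponents(m, 8L)), 1L)
  ## labels numbered by first pixel in column-major order
  m2 <- matrix(0, 6, 6); m2[5:6, 1] <- 1; m2[1, 4:5] <- 1
  l2 <- labelComponents(m2, 8L)
  expect_equal(l2[5, 1], 1L)
  expect_equal(l2[1, 4], 2L)
})

test_that("segmentation confines labels to the mask and is deterministic", {
  set.seed(5)
  img <- matrix(rpois(120 * 120, 20), 120, 120)
  img[20:28, 20:34] <- 800    # inside mask
  img[100:110, 100:110] <- 800  # entirely outside mask
  image <- IntensityImage(img, bitDepth = 16L)
  mask <- CellMask(makeDisc(40, 120, center = c(45, 45)) > 0)
  seg <- segmentAdhesions(image, mask)
  expect_equal(nLabels(seg), 1L)
  expect_true(all(pixels(mask)[labelMatrix(seg) > 0]))
  ## identical inputs give identical label maps
  seg2 <- segmentAdhesions(image, mask)
  expect_identical(labelMatrix(seg), labelMatrix(seg2))
  ## threshold is echoed for provenance
  expect_true(is.finite(seg@metadata$threshold))
  ## dimension mismatch
  expect_error(segmentAdhesions(IntensityImage(matrix(0, 5, 5)), mask),
               "ShapeMismatch")
})

test_that("shrinking the mask never increases labels or label sizes", {
  sc <- generateScene(smallSceneConfig(seed = 9))
  big <- sc$mask
  seg1 <- segmentAdhesions(sc$image, big)
  ## shrink: erode the mask to half radius
  small <- CellMask(makeDisc(40, 200, center = c(100, 100)) > 0)
  seg2 <- segmentAdhesions(sc$image, small)
  expect_lte(nLabels(seg2), nLabels(seg1))
  expect_lte(sum(labelMatrix(seg2) > 0), sum(labelMatrix(seg1) > 0))
})

test_that("watershed on/off changes splitting, not total coverage", {
  sc <- generateScene(smallSceneConfig(seed = 4))
  on <- segmentAdhesions(sc$image, sc$mask,
                         segmentationConfig(watershedEnabled = TRUE))
  off <- segmentAdhesions(sc$image, sc$mask,
                          segmentationConfig(watershedEnabled = FALSE))
  expect_gte(nLabels(on), nLabels(off))
  ## union may differ only by watershed-line pixels
  expect_lte(sum(labelMatrix(off) > 0) - sum(labelMatrix(on) > 0),
             nLabels(on) * 60)
  expect_true(all(labelMatrix(off)[labelMatrix(on) > 0] > 0))
})
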