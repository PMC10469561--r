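## measure a single binary shape against a full-frame mask
measureShape <- function(bin, mask = fullMask(nrow(bin), ncol(bin))) {
  lab <- matrix(0L, nrow(bin), ncol(bin))
  lab[bin > 0] <- 1L
  measureAdhesions(faquant:::LabelMap(lab), mask)
}

test_that("reference shapes give the expected morphometrics", {
  ## solid 10(row) x 40(col) rectangle: horizontal major axis
  rect <- matrix(0, 30, 60); rect[11:20, 11:50] <- 1
  r <- measureShape(rect)
  expect_equal(r$fa_area_px, 400L)
  expect_equal(r$orientation_deg, 0, tolerance = 1e-9)
  expect_equal(r$ar, 4.00, tolerance = 0.05 / 4)
  expect_equal(r$x0_px, (10 + 49) / 2)   # 0-based centroid
  expect_equal(r$y0_px, (10 + 19) / 2)
  ## solid disc r = 20: isotropic, sf near 4*pi
  disc <- makeDisc(20)
  d <- measureShape(disc)
  expect_lte(d$ar, 1.02)
  expect_equal(d$sf, 4 * pi, tolerance = 0.05)
  ## single pixel: degenerate tie-breaks
  px <- matrix(0, 5, 5); px[3, 3] <- 1
  s <- measureShape(px)
  expect_equal(s$fa_area_px, 1L)
  expect_equal(s$ar, 1)
  expect_equal(s$orientation_deg, 0)
  expect_gt(s$perim_px, 0)
})

test_that("area, centroid and moments match brute-force accumulation", {
  set.seed(21)
  for (i in 1:30) {
    bin <- randomBlob()
    ## largest component only (blob may be multi-part)
    lab <- labelComponents(bin, 8L)
    keep <- which.max(tabulate(lab[lab > 0]))
    bin <- matrix(as.numeric(lab == keep), nrow(bin), ncol(bin))
    r <- measureShape(bin)
    o <- bruteRegionStats(bin)
    expect_identical(r$fa_area_px, o$area)
    expect_identical(r$x0_px, o$x0)
    expect_identical(r$y0_px, o$y0)
  }
})

test_that("orientation is rotation-equivariant and ar/sf are invariant", {
  set.seed(22)
  base <- matrix(0, 60, 60); base[26:35, 11:50] <- 1  # wide rectangle
  ell <- makeDiscs(rbind(c(30, 20, 8), c(30, 30, 8), c(30, 40, 8)), 60, 60)
  for (bin in list(base, ell)) {
    r0 <- measureShape(bin)
    ## 90 deg rotation: transpose + reverse rows maps (r,c) -> (c, nr+1-r)
    rot <- t(bin)[, rev(seq_len(nrow(bin)))]
    r90 <- measureShape(rot)
    dth <- abs(r90$orientation_deg - r0$orientation_deg)
    expect_equal(min(abs(dth - 90), abs(dth - 270)), 0, tolerance = 1e-6)
    expect_equal(r90$ar, r0$ar, tolerance = 1e-9)
    expect_equal(r90$fa_area_px, r0$fa_area_px)
    expect_equal(r90$sf, r0$sf, tolerance = 1e-6)
  }
})

test_that("translation moves the centroid and nothing else", {
  bin <- matrix(0, 80, 80); bin[20:27, 15:44] <- 1
  sh <- matrix(0, 80, 80); sh[40:47, 30:59] <- 1
  a <- measureShape(bin); b <- measureShape(sh)
  expect_equal(b$x0_px - a$x0_px, 15)
  expect_equal(b$y0_px - a$y0_px, 20)
  expect_equal(b$ar, a$ar, tolerance = 1e-12)
  expect_equal(b$sf, a$sf, tolerance = 1e-9)
  expect_equal(b$orientation_deg, a$orientation_deg, tolerance = 1e-12)
})

test_that("peripheral classification applies the strict 10% rule", {
  expect_identical(classifyPeripheral(c(5, 9.9, 10, 50), 100),
                   c(TRUE, TRUE, FALSE, FALSE))
  expect_true(classifyPeripheral(0, 100))
  expect_true(classifyPeripheral(0, 100, periphFrac = 0.01))
  ## configurable fraction
  expect_identical(classifyPeripheral(c(15, 25), 100, periphFrac = 0.2),
                   c(TRUE, FALSE))
  expect_error(classifyPeripheral(5, 100, periphFrac = 0), "InvalidFraction")
  expect_error(classifyPeripheral(5, 100, periphFrac = 1), "InvalidFraction")
  expect_error(classifyPeripheral(5, 0), "InvalidFraction")
})

test_that("rel_orientation folds into [0, 90] against the centroid angle", {
  ## horizontal bar placed due east of the mask centroid: radially aligned
  mask <- CellMask(makeDisc(45, 100, center = c(50, 50)) > 0)
  lab <- matrix(0L, 100, 100); lab[49:51, 66:85] <- 1L
  r <- measureAdhesions(faquant:::LabelMap(lab), mask)
  expect_lt(r$rel_orientation_deg, 5)
  ## vertical bar due east: perpendicular
  lab2 <- matrix(0L, 100, 100); lab2[41:60, 74:76] <- 1L
  r2 <- measureAdhesions(faquant:::LabelMap(lab2), mask)
  expect_gt(r2$rel_orientation_deg, 85)
  expect_lte(r2$rel_orientation_deg, 90)
})

test_that("area filtering keeps the requested range in order", {
  recs <- data.frame(label = 1:3, fa_area_px = c(1L, 5L, 50L))
  expect_equal(filterByArea(recs, 4)$fa_area_px, c(5L, 50L))
  expect_equal(filterByArea(recs, 0, Inf), recs)
  recs2 <- data.frame(label = 1:2, fa_area_px = c(2000L, 30L))
  expect_equal(filterByArea(recs2, 1, 1000)$fa_area_px, 30L)
  expect_error(filterByArea(recs, 10, 5), "InvalidRange")
})

test_that("image summary arithmetic is exact", {
  mask <- fullMask(100)
  lab <- matrix(0L, 100, 100)
  lab[1:10, 1:10] <- 1L            # 100 px
  lab[41:60, 41:55] <- 2L          # 300 px
  recs <- measureAdhesions(faquant:::LabelMap(lab), mask)
  s <- summarizeImage(recs, mask)
  expect_identical(s$mask_area_px, 10000L)
  expect_identical(s$no_fas, 2L)
  expect_identical(s$area_fraction, 0.04)
  expect_equal(s$area_fraction * s$mask_area_px,
               as.numeric(sum(recs$fa_area_px)))
  expect_equal(s$mean_fa_area_px, 200)
  expect_equal(s$std_fa_area_px, sd(c(100, 300)))
  ## 3 FAs, 1 peripheral
  r3 <- data.frame(fa_area_px = c(10L, 10L, 10L), perim_px = 1, x0_px = 0,
                   y0_px = 0, orientation_deg = 0, ar = 1, sf = 13,
                   dist_px = 0, angle_deg = 0, rel_orientation_deg = 0,
                   is_peripheral = c(TRUE, FALSE, FALSE))
  expect_equal(summarizeImage(r3, mask)$frac_periph_fas, 1 / 3)
  ## empty
  s0 <- summarizeImage(measureAdhesions(
    faquant:::LabelMap(matrix(0L, 100, 100)), mask), mask)
  expect_identical(s0$no_fas, 0L)
  expect_identical(s0$area_fraction, 0)
  expect_true(is.na(s0$frac_periph_fas))
})

test_that("physical conversion annotates without touching pixel columns", {
  recs <- data.frame(fa_area_px = 400L, perim_px = 100, x0_px = 0, y0_px = 0,
                     orientation_deg = 0, ar = 4, sf = 25, dist_px = 5,
                     angle_deg = 0, rel_orientation_deg = 0,
                     is_peripheral = FALSE)
  out <- suppressMessages(convertToPhysical(recs, 0.2))
  expect_equal(out$fa_area_um2, 16.0)
  expect_equal(out$perim_um, 20.0)
  expect_identical(out$fa_area_px, recs$fa_area_px)
  expect_identical(out$perim_px, recs$perim_px)
  expect_error(convertToPhysical(recs, -1), "InvalidPixelSize")
})
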