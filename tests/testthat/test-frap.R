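test_that("normalization subtracts background and pins pre-bleach to 1", {
  ## pre-bleach {100, 102}, constant background 2 -> subtracted mean 99
  times <- seq(0, 90, by = 15)
  I <- c(100, 102, 30, 50, 60, 65, 68)
  bl <- FRAPCurve(times, I, role = "bleached", nPre = 2)
  norm <- normalizeFrap(bl, background = 2)
  v <- frapIntensities(norm)
  expect_equal(mean(v[1:2]), 1, tolerance = 1e-12)
  expect_equal(v[1:2], c(98, 100) / 99)
  expect_equal(v[3], 28 / 99)
  ## without a reference, output is just background-subtracted + normalized
  expect_equal(frapRole(norm), "normalized")
})

test_that("reference correction flattens an unbleached control exactly", {
  lambda <- 0.002
  cv <- generateFrapCurves(k = 0.02, f0 = 1, plateau = 1,
                           bleachLambda = lambda, scale = 500)
  ## bleached curve here is an unbleached control (f0 = plateau = 1) that
  ## decays only through acquisition bleaching
  norm <- normalizeFrap(cv$bleached, background = 0,
                        reference = cv$reference)
  expect_lt(max(abs(frapIntensities(norm) - 1)), 1e-9)
})

test_that("normalization is idempotent and scale-invariant", {
  cv <- generateFrapCurves(k = 0.02, f0 = 0.2, plateau = 0.8, scale = 350,
                           background = 40)
  n1 <- normalizeFrap(cv$bleached, cv$background)
  n2 <- normalizeFrap(n1, background = 0)
  expect_equal(frapIntensities(n1), frapIntensities(n2), tolerance = 1e-12)
  ## scaling raw intensities by c > 0 changes nothing after normalization
  big <- FRAPCurve(frapTimes(cv$bleached),
                   frapIntensities(cv$bleached) * 7.3,
                   role = "bleached", nPre = 2)
  bgBig <- FRAPCurve(frapTimes(cv$background),
                     frapIntensities(cv$background) * 7.3,
                     role = "background", nPre = 2)
  n3 <- normalizeFrap(big, bgBig)
  expect_equal(frapIntensities(n3), frapIntensities(n1), tolerance = 1e-9)
  ## degenerate pre-bleach
  zero <- FRAPCurve(1:6, c(0, 0, 1, 2, 3, 4), role = "bleached", nPre = 2)
  expect_error(normalizeFrap(zero, background = 0), "ZeroPreBleach")
})

test_that("one-phase fit recovers noiseless parameters to 1e-6", {
  cv <- generateFrapCurves(k = 0.02, f0 = 0.2, plateau = 0.8)
  fit <- fitOnePhase(normalizeFrap(cv$bleached, cv$background))
  expect_equal(recoveryRate(fit), 0.02, tolerance = 1e-6)
  expect_equal(fit@f0, 0.2, tolerance = 1e-6)
  expect_equal(fit@plateau, 0.8, tolerance = 1e-6)
  expect_equal(halfTime(fit), log(2) / 0.02, tolerance = 1e-6)
  expect_equal(mobileFraction(fit), 0.75, tolerance = 1e-6)
  ## half-time identity holds exactly by construction
  expect_equal(halfTime(fit) * recoveryRate(fit), log(2), tolerance = 1e-12)
})

test_that("flat curves are reported as no recovery, not a spurious rate", {
  flat <- FRAPCurve(seq(0, 120, 15), c(1, 1, rep(0.2, 7)),
                    role = "normalized", nPre = 2)
  expect_error(fitOnePhase(flat), "NoRecovery")
  short <- FRAPCurve(seq(0, 45, 15), c(1, 1, 0.2, 0.5),
                     role = "normalized", nPre = 2)
  expect_error(fitOnePhase(short), "InsufficientData")
})

test_that("bleach-frame detection finds the >50% drop", {
  cv <- generateFrapCurves(k = 0.02, f0 = 0.2, plateau = 0.9, preN = 4)
  expect_equal(detectBleachFrame(cv$bleached), 4L)
  ## shallow drop: falls back to stored nPre
  mild <- FRAPCurve(1:6, c(1, 1, 0.8, 0.85, 0.9, 0.92),
                    role = "bleached", nPre = 2)
  expect_equal(detectBleachFrame(mild), 2L)
})

test_that("averaging fits the mean curve and brackets mixed rates", {
  cv <- generateFrapCurves(k = 0.02, f0 = 0.2, plateau = 0.8)
  n <- normalizeFrap(cv$bleached, cv$background)
  same <- averageAndFit(list(n, n))
  single <- fitOnePhase(n)
  expect_equal(recoveryRate(same$average), recoveryRate(single),
               tolerance = 1e-9)
  ## k = 0.01 and 0.03 with equal amplitudes: averaged-curve k in between
  a <- normalizeFrap(generateFrapCurves(0.01, 0.2, 0.8)$bleached, 0)
  b <- normalizeFrap(generateFrapCurves(0.03, 0.2, 0.8)$bleached, 0)
  mix <- averageAndFit(list(a, b))
  expect_gt(recoveryRate(mix$average), 0.01)
  expect_lt(recoveryRate(mix$average), 0.03)
  expect_length(mix$perCurve, 2L)
  expect_error(averageAndFit(list(n)), "InsufficientCurves")
  shifted <- FRAPCurve(frapTimes(n) + 1, frapIntensities(n),
                       role = "normalized", nPre = 2)
  expect_error(averageAndFit(list(n, shifted)), "GridMismatch")
})

test_that("FRAP table IO and the file-level driver work end to end", {
  dir <- withr::local_tempdir()
  set.seed(77)
  cv1 <- generateFrapCurves(0.02, 0.2, 0.8, noiseSd = 0.01, scale = 100,
                            background = 10, seed = 101)
  cv2 <- generateFrapCurves(0.025, 0.25, 0.85, noiseSd = 0.01, scale = 100,
                            background = 10, seed = 102)
  df <- data.frame(time_s = frapTimes(cv1$bleached),
                   roi1 = frapIntensities(cv1$bleached),
                   roi2 = frapIntensities(cv2$bleached),
                   ref = frapIntensities(cv1$reference),
                   bg = frapIntensities(cv1$background))
  path <- file.path(dir, "frap.csv")
  write.csv(df, path, row.names = FALSE)
  res <- frapFitFile(path, bleached = c("roi1", "roi2"), reference = "ref",
                     background = "bg", outDir = dir)
  expect_true(file.exists(file.path(dir, "frap fits.csv")))
  expect_true(file.exists(file.path(dir, "normalized curves.csv")))
  summ <- read.csv(file.path(dir, "frap fits.csv"))
  expect_equal(summ$roi, c("roi1", "roi2", "average"))
  expect_true(all(is.finite(summ$k_per_s)))
  expect_equal(summ$half_time_s[1], log(2) / summ$k_per_s[1],
               tolerance = 1e-4)
  ## the uncorrected branch: no reference column supplied
  res2 <- frapFitFile(path, bleached = "roi1", background = "bg",
                      outDir = file.path(dir, "noref"))
  expect_s4_class(res2$fits$roi1, "FRAPFit")
  expect_error(readFrapTable(path, bleached = "missing"), "InvalidTable")
})
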