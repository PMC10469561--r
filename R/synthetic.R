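## Ground-truth scene and FRAP-curve generators. Scenes emulate the image
## statistics the segmentation assumes: elliptical adhesions (1-10 um long
## at ~0.2 um/px) inside a convex-ish cell mask, Gaussian PSF blur, smooth
## background, Poisson shot noise plus Gaussian read noise. Curves follow
## single-exponential recovery with optional acquisition bleaching and a
## constant background offset.

#' Scene generator configuration
#'
#' Defines the statistical conditions of a synthetic adhesion scene. The
#' defaults render a 400 x 400 16-bit image at 0.2 um/px with a disc-shaped
#' cell of radius 160 px containing 30 non-overlapping elliptical adhesions
#' whose areas are lognormal (meanlog = log(150), sdlog = 0.3, i.e. mostly
#' 80-300 px, ~1.6-5 um long) and aspect ratios uniform on [2, 5] — the
#' regime in which orientation is well defined. Signal 1000 counts over a
#' 100-count background with a mild horizontal ramp, PSF sigma 1 px,
#' Poisson shot noise and read noise sd 10 give a realized SNR of ~26.
#'
#' @param imageSize c(rows, cols), default c(400, 400).
#' @param pixelSizeUm Pixel size (um/px), default 0.2.
#' @param cellShape "disc" or "blob" (Fourier-perturbed disc, exercising
#'   concave masks).
#' @param cellRadiusPx Cell radius (px), default 160.
#' @param nFAs Number of adhesions, default 30.
#' @param areaLogMean,areaLogSd Lognormal area parameters (px).
#' @param arRange Aspect-ratio range, uniform, default c(2, 5).
#' @param orientationMode "uniform" or "radial" (aligned toward the cell
#'   centroid with wrapped-normal scatter of concentration \code{kappa}).
#' @param kappa Radial-alignment concentration, default 8.
#' @param faIntensity Adhesion signal amplitude (counts), default 1000.
#' @param backgroundOffset,backgroundGradient Smooth background: constant
#'   offset plus a horizontal linear ramp of the given amplitude.
#' @param psfSigmaPx Gaussian PSF sigma (px), default 1.
#' @param poissonNoise Apply Poisson shot noise to signal + background.
#' @param readNoiseSd Additive Gaussian read noise sd (counts), default 10.
#' @param bitDepth Output bit depth, default 16.
#' @param minGapPx Minimum gap between adhesion bounding circles (px),
#'   default 6, so PSF tails do not bridge neighbors.
#' @param seed RNG seed; same seed gives bit-identical scenes.
#' @return A list of class \code{"SceneConfig"}.
#' @export
sceneConfig <- function(imageSize = c(400L, 400L),
                        pixelSizeUm = 0.2,
                        cellShape = c("disc", "blob"),
                        cellRadiusPx = 160,
                        nFAs = 30L,
                        areaLogMean = log(150),
                        areaLogSd = 0.3,
                        arRange = c(2, 5),
                        orientationMode = c("uniform", "radial"),
                        kappa = 8,
                        faIntensity = 1000,
                        backgroundOffset = 100,
                        backgroundGradient = 20,
                        psfSigmaPx = 1.0,
                        poissonNoise = TRUE,
                        readNoiseSd = 10,
                        bitDepth = 16L,
                        minGapPx = 6,
                        seed = 1L) {
  cfg <- list(imageSize = as.integer(imageSize),
              pixelSizeUm = pixelSizeUm,
              cellShape = match.arg(cellShape),
              cellRadiusPx = cellRadiusPx,
              nFAs = as.integer(nFAs),
              areaLogMean = areaLogMean, areaLogSd = areaLogSd,
              arRange = arRange,
              orientationMode = match.arg(orientationMode),
              kappa = kappa,
              faIntensity = faIntensity,
              backgroundOffset = backgroundOffset,
              backgroundGradient = backgroundGradient,
              psfSigmaPx = psfSigmaPx,
              poissonNoise = isTRUE(poissonNoise),
              readNoiseSd = readNoiseSd,
              bitDepth = as.integer(bitDepth),
              minGapPx = minGapPx,
              seed = as.integer(seed))
  stopifnot(cfg$nFAs >= 0L, cfg$cellRadiusPx > 0, all(cfg$imageSize >= 1L),
            cfg$arRange[1] >= 1, cfg$arRange[2] >= cfg$arRange[1],
            cfg$faIntensity > 0, cfg$readNoiseSd >= 0)
  class(cfg) <- "SceneConfig"
  cfg
}

## rasterize the cell mask (disc, or low-order Fourier-perturbed disc)
renderCellMask <- function(cfg) {
  nr <- cfg$imageSize[1]; nc <- cfg$imageSize[2]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  rw <- matrix(seq_len(nr), nr, nc)
  cl <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dy <- rw - cy; dx <- cl - cx
  rad <- sqrt(dx^2 + dy^2)
  if (cfg$cellShape == "disc") {
    rad <= cfg$cellRadiusPx
  } else {
    theta <- atan2(dy, dx)
    ## bounded low-order harmonics keep the outline blob-like, not spiky
    amp <- stats::runif(4, 0, 0.15 / (2:5))
    phi <- stats::runif(4, 0, 2 * pi)
    rTheta <- cfg$cellRadiusPx *
      (1 + Reduce(`+`, lapply(1:4, function(k)
        amp[k] * cos((k + 1) * theta + phi[k]))))
    rad <= rTheta
  }
}

## pixels of an analytic ellipse: center (xc, yc) 1-based, semi-axes a >= b,
## major axis at angle theta (radians, x toward +columns, y toward +rows)
rasterEllipse <- function(xc, yc, a, b, theta, nr, nc) {
  r0 <- max(1L, floor(yc - a)); r1 <- min(nr, ceiling(yc + a))
  c0 <- max(1L, floor(xc - a)); c1 <- min(nc, ceiling(xc + a))
  rows <- r0:r1; cols <- c0:c1
  dy <- matrix(rows - yc, length(rows), length(cols))
  dx <- matrix(cols - xc, length(rows), length(cols), byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  cbind(row = rows[idx[, 1]], col = cols[idx[, 2]])
}

#' Generate a ground-truth adhesion scene
#'
#' Renders the cell mask, places elliptical adhesions fully inside it by
#' rejection sampling (pairwise non-overlapping with a configurable gap),
#' rasterizes them, convolves with the Gaussian PSF, adds the smooth
#' background and the shot/read noise, and quantizes to the configured bit
#' depth. The returned truth table holds the analytic parameters of every
#' adhesion before rasterization. The same seed yields bit-identical
#' output.
#'
#' @param config A [sceneConfig()] list.
#' @return A list: \code{image} ([IntensityImage-class]), \code{mask}
#'   ([CellMask-class]), \code{truth} (data.frame with columns \code{x0_px},
#'   \code{y0_px}, \code{area_px}, \code{ar}, \code{orientation_deg},
#'   \code{dist_px}, \code{is_peripheral}) and \code{snr} (realized
#'   signal-to-noise ratio, signal amplitude over total noise sd at an
#'   adhesion pixel).
#' @export
generateScene <- function(config = sceneConfig()) {
  cfg <- config
  set.seed(cfg$seed)
  nr <- cfg$imageSize[1]; nc <- cfg$imageSize[2]
  maskBin <- renderCellMask(cfg)
  mask <- CellMask(maskBin)
  dm <- distanceMap(mask)

  truth <- data.frame(x0_px = numeric(0), y0_px = numeric(0),
                      area_px = numeric(0), ar = numeric(0),
                      orientation_deg = numeric(0), dist_px = numeric(0),
                      is_peripheral = logical(0))
  signal <- matrix(0, nr, nc)
  placed <- NULL  # columns: xc, yc, a (bounding radius)
  ctr <- maskCentroid(mask)
  attempts <- 0L
  maxAttempts <- max(200L * cfg$nFAs, 1000L)
  while (nrow(truth) < cfg$nFAs) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      faStop("PlacementFailure",
             "placed %d of %d adhesions after %d attempts; reduce nFAs or sizes",
             nrow(truth), cfg$nFAs, attempts)
    area <- stats::rlnorm(1, cfg$areaLogMean, cfg$areaLogSd)
    ar <- stats::runif(1, cfg$arRange[1], cfg$arRange[2])
    a <- sqrt(area * ar / pi)
    b <- a / ar
    ## candidate center: uniform over pixels deep enough inside the mask
    ok <- which(dm > a + 2)
    if (!length(ok)) next
    pick <- ok[sample.int(length(ok), 1L)]
    yc <- ((pick - 1L) %% nr) + 1L
    xc <- ((pick - 1L) %/% nr) + 1L
    if (!is.null(placed)) {
      dd <- sqrt((placed[, 1] - xc)^2 + (placed[, 2] - yc)^2)
      if (any(dd < placed[, 3] + a + cfg$minGapPx)) next
    }
    angDeg <- if (cfg$orientationMode == "uniform") {
      stats::runif(1, -90, 90)
    } else {
      radial <- atan2(yc - 1 - ctr[["y"]], xc - 1 - ctr[["x"]]) * 180 / pi
      d <- radial + stats::rnorm(1, 0, (180 / pi) / sqrt(cfg$kappa))
      d <- d %% 180
      if (d >= 90) d - 180 else d
    }
    px <- rasterEllipse(xc, yc, a, b, angDeg * pi / 180, nr, nc)
    signal[px] <- signal[px] + cfg$faIntensity
    placed <- rbind(placed, c(xc, yc, a))
    dist <- dm[yc, xc]
    truth <- rbind(truth, data.frame(
      x0_px = xc - 1, y0_px = yc - 1, area_px = pi * a * b, ar = ar,
      orientation_deg = angDeg, dist_px = dist,
      is_peripheral = dist < 0.1 * maxBorderDist(mask)))
  }

  ramp <- matrix(seq(0, 1, length.out = nc), nr, nc, byrow = TRUE)
  clean <- blurPadded(signal, cfg$psfSigmaPx) +
    cfg$backgroundOffset + cfg$backgroundGradient * ramp
  noisy <- if (cfg$poissonNoise) {
    stats::rpois(length(clean), lambda = pmax(clean, 0))
  } else {
    as.vector(clean)
  }
  noisy <- noisy + if (cfg$readNoiseSd > 0) {
    stats::rnorm(length(clean), 0, cfg$readNoiseSd)
  } else 0
  img <- matrix(pmin(pmax(round(noisy), 0), 2^cfg$bitDepth - 1), nr, nc)
  snr <- cfg$faIntensity /
    sqrt(cfg$faIntensity + cfg$backgroundOffset +
         cfg$backgroundGradient / 2 + cfg$readNoiseSd^2)
  list(image = IntensityImage(img, bitDepth = cfg$bitDepth,
                              pixelSizeUm = cfg$pixelSizeUm),
       mask = mask, truth = truth, snr = snr)
}

#' Generate a synthetic FRAP ROI set
#'
#' Produces the three ROI curves of a single-exponential FRAP experiment on
#' a common time grid: a bleached ROI following one-phase association
#' recovery, a reference ROI tracking acquisition bleaching, and a
#' background ROI. \code{preN} pre-bleach frames at full intensity are
#' prepended; the bleach occurs between frames \code{preN} and
#' \code{preN + 1}. With \code{bleachLambda = 0}, no background and no
#' noise, the bleached curve equals the closed form exactly.
#'
#' @param k Recovery rate (per second, > 0).
#' @param f0 Normalized intensity right after the bleach (0 <= f0 <=
#'   plateau).
#' @param plateau Normalized recovery asymptote (<= 1).
#' @param preN Number of pre-bleach frames, default 2.
#' @param bleachLambda Acquisition-bleaching rate (per second), default 0.
#' @param background Constant background offset, default 0.
#' @param noiseSd Additive Gaussian noise sd, default 0.
#' @param dt Frame interval (s), default 15 (one frame every 15 s).
#' @param duration Post-bleach duration (s), default 300 (5 min).
#' @param scale Intensity scale factor (arbitrary units), default 1.
#' @param seed Optional RNG seed for the noise.
#' @return A named list of [FRAPCurve-class]: \code{bleached},
#'   \code{reference}, \code{background}.
#' @export
generateFrapCurves <- function(k, f0, plateau, preN = 2L, bleachLambda = 0,
                               background = 0, noiseSd = 0, dt = 15,
                               duration = 300, scale = 1, seed = NULL) {
  if (k <= 0 || f0 < 0 || f0 > plateau || plateau > 1)
    faStop("InvalidKinetics", "need k > 0 and 0 <= f0 <= plateau <= 1")
  if (!is.null(seed)) set.seed(seed)
  nPost <- floor(duration / dt) + 1L
  times <- (seq_len(preN + nPost) - 1L) * dt
  post <- seq.int(preN + 1L, preN + nPost)
  s <- times[post] - times[post][1L]
  rec <- f0 + (plateau - f0) * (1 - exp(-k * s))
  decay <- exp(-bleachLambda * times)
  noise <- function() if (noiseSd > 0)
    stats::rnorm(length(times), 0, noiseSd) else 0
  bleachedI <- c(rep(1, preN), rec) * decay * scale + background + noise()
  referenceI <- decay * scale + background + noise()
  backgroundI <- rep(background, length(times)) + noise()
  list(
    bleached = FRAPCurve(times, bleachedI, role = "bleached", nPre = preN),
    reference = FRAPCurve(times, referenceI, role = "reference", nPre = preN),
    background = FRAPCurve(times, backgroundI, role = "background",
                           nPre = preN))
}
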