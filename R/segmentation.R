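## Adhesion segmentation: rolling-ball background subtraction -> automatic
## thresholding -> distance-transform watershed -> masked component
## labeling. Fully deterministic.

#' Rolling-ball background subtraction
#'
#' Estimates the smooth image background by grayscale opening with a disc
#' structuring element of the given radius and subtracts it. The radius
#' should be large relative to adhesion size (default 50 px, comfortably
#' above the ~67 px major axis of a 10 um adhesion at 0.15 um/px) so that
#' adhesions are not eroded into the background estimate. Constant offsets
#' are removed entirely; the operation is invariant to adding a constant.
#'
#' @param image An [IntensityImage-class] (or plain matrix).
#' @param radiusPx Structuring-element radius in pixels (> 0, default 50).
#' @return Background-subtracted image of the same class and bit depth.
#' @export
subtractBackground <- function(image, radiusPx = 50) {
  if (radiusPx <= 0) faStop("InvalidRadius", "radiusPx must be > 0")
  m <- if (is(image, "IntensityImage")) pixels(image) else image
  size <- 2L * as.integer(floor(radiusPx)) + 1L
  ## EBImage morphology operates on [0, 1] intensities; a flat structuring
  ## element commutes with linear rescaling, so scale, open, scale back
  s <- max(m, 1)
  bg <- as.matrix(EBImage::opening(m / s, EBImage::makeBrush(size, "disc"))) * s
  ## the opening selects actual pixel values, so the difference is integer
  ## up to rescaling round-off; round to keep the raster integer-valued
  out <- round(pmax(m - bg, 0))
  if (is(image, "IntensityImage"))
    IntensityImage(out, bitDepth = bitDepth(image),
                   pixelSizeUm = pixelSizeUm(image))
  else out
}

## Otsu: exhaustive maximization of between-class variance over all
## candidate thresholds, vectorized over the histogram; ties broken toward
## the lower threshold. Foreground = values strictly greater than the
## returned threshold.
otsuThreshold <- function(values, nLevels) {
  h <- tabulate(values + 1L, nbins = nLevels)
  total <- sum(h)
  lev <- 0:(nLevels - 1L)
  w0 <- cumsum(h)
  s0 <- cumsum(h * lev)
  mu <- s0[nLevels] / total
  ## threshold t: class 0 = values <= t, class 1 = values > t
  w0n <- w0 / total
  valid <- w0n > 0 & w0n < 1
  sigma2 <- rep(-Inf, nLevels)
  mu0 <- s0[valid] / w0[valid]
  sigma2[valid] <- w0n[valid] / (1 - w0n[valid]) * (mu0 - mu)^2
  lev[which.max(sigma2)]  # which.max takes the first (lowest) maximizer
}

## Triangle method: distance from the histogram to the peak->far-tail chord.
triangleThreshold <- function(values, nLevels) {
  h <- tabulate(values + 1L, nbins = nLevels)
  peak <- which.max(h)
  nz <- range(which(h > 0))
  ## far tail = histogram end farther from the peak
  tail <- if ((peak - nz[1]) > (nz[2] - peak)) nz[1] else nz[2]
  if (tail == peak) return(peak - 1L)
  span <- tail - peak
  idx <- peak:tail
  ## perpendicular distance of (idx, h[idx]) from chord peak->tail
  dx <- span
  dy <- h[tail] - h[peak]
  d <- abs(dy * (idx - peak) - dx * (h[idx] - h[peak])) / sqrt(dx^2 + dy^2)
  idx[which.max(d)] - 1L
}

#' Automatic image thresholding
#'
#' Chooses a global threshold with Otsu's between-class-variance criterion
#' (default) or the triangle method, or applies a fixed value. Foreground is
#' the set of pixels strictly above the threshold; ties at the threshold are
#' background. A constant image has no separable classes: an empty
#' foreground is returned with a warning rather than an error.
#'
#' @param image [IntensityImage-class] or integer-valued matrix.
#' @param method "otsu", "triangle" or "fixed".
#' @param fixedThreshold Threshold when \code{method = "fixed"}.
#' @param nLevels Number of gray levels (defaults to \code{2^bitDepth} for
#'   an IntensityImage, else \code{max + 1}).
#' @return A list with \code{binary} (logical matrix) and \code{threshold}
#'   (the chosen value; \code{NA} for a degenerate constant image).
#' @export
autoThreshold <- function(image, method = c("otsu", "triangle", "fixed"),
                          fixedThreshold = NA_real_, nLevels = NULL) {
  method <- match.arg(method)
  m <- if (is(image, "IntensityImage")) pixels(image) else image
  if (is.null(nLevels)) {
    nLevels <- if (is(image, "IntensityImage")) 2L^bitDepth(image)
               else as.integer(max(m)) + 1L
  }
  if (method == "fixed") {
    if (is.na(fixedThreshold))
      faStop("InvalidThreshold", "fixedThreshold required for method 'fixed'")
    return(list(binary = m > fixedThreshold, threshold = fixedThreshold))
  }
  vals <- as.integer(m)
  if (min(vals) == max(vals)) {
    warning("DegenerateHistogram: constant image, returning empty foreground",
            call. = FALSE)
    return(list(binary = matrix(FALSE, nrow(m), ncol(m)), threshold = NA_real_))
  }
  th <- switch(method,
    otsu = otsuThreshold(vals, nLevels),
    triangle = triangleThreshold(vals, nLevels))
  list(binary = m > th, threshold = as.numeric(th))
}

#' Distance-transform watershed splitting
#'
#' Splits touching objects in a binary raster: the Euclidean distance map of
#' the foreground is smoothed with a Gaussian, maxima shallower than
#' \code{hMaxima} are suppressed (realized as the flooding merge tolerance),
#' and the negated distance map is flooded from the surviving maxima.
#' Pixels where two basins meet are assigned to background, forming
#' one-pixel watershed lines, and the result is relabeled so every label is
#' a single connected component. The number of labels never falls below the
#' plain connected-component count, and no pixel outside the input
#' foreground is ever labeled.
#'
#' @param binary Logical (or 0/1) matrix.
#' @param smoothingSigmaPx Gaussian sigma for the distance map (px).
#' @param hMaxima Suppression depth for shallow maxima.
#' @param connectivity 4 or 8, used for line removal and relabeling
#'   (flooding itself explores the full 3x3 neighborhood).
#' @return A [LabelMap-class].
#' @export
watershedSplit <- function(binary, smoothingSigmaPx = 1.0, hMaxima = 1.0,
                           connectivity = 8L) {
  fg <- binary > 0
  if (!any(fg))
    return(LabelMap(matrix(0L, nrow(fg), ncol(fg))))
  dm <- euclideanDistMap(fg)
  dms <- blurPadded(dm, smoothingSigmaPx)
  dms[!fg] <- 0
  ws <- as.matrix(EBImage::watershed(dms, tolerance = hMaxima, ext = 1L))
  storage.mode(ws) <- "integer"
  ## assign watershed lines to background: drop each pixel that touches a
  ## smaller positive label (one-sided, so the line is one pixel wide)
  ws[neighborHasSmallerLabel(ws, connectivity)] <- 0L
  LabelMap(labelComponents(ws > 0, connectivity))
}

## TRUE where a positive-label pixel has a neighbor with a smaller positive
## label (at the given connectivity)
neighborHasSmallerLabel <- function(lab, connectivity = 8L) {
  nr <- nrow(lab); nc <- ncol(lab)
  big <- matrix(0L, nr + 2L, nc + 2L)
  big[2:(nr + 1), 2:(nc + 1)] <- lab
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L)
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  hit <- matrix(FALSE, nr, nc)
  for (o in offs) {
    nb <- big[(2:(nr + 1)) + o[1], (2:(nc + 1)) + o[2]]
    hit <- hit | (nb > 0L & nb < lab)
  }
  hit & lab > 0L
}

#' Segment adhesions within a cell mask
#'
#' The full segmentation pipeline: background subtraction, automatic
#' thresholding (computed from the pixels inside the mask's bounding box, so
#' large empty fields outside the cell do not bias the histogram), optional
#' watershed splitting, then intersection of the labels with the cell mask.
#' Labels left empty by the masking are dropped and the rest renumbered
#' consecutively; a label that the mask splits into pieces keeps a single
#' identity. Identical inputs always give identical label maps.
#'
#' @param image [IntensityImage-class]; same dimensions as the mask.
#' @param mask [CellMask-class].
#' @param config [SegmentationConfig-class]; see [segmentationConfig()].
#' @return A [LabelMap-class] whose \code{metadata} records the chosen
#'   threshold and the configuration.
#' @examples
#' sc <- generateScene(sceneConfig(nFAs = 5, imageSize = c(128, 128),
#'                                 cellRadiusPx = 50, seed = 1))
#' seg <- segmentAdhesions(sc$image, sc$mask, segmentationConfig())
#' nLabels(seg)
#' @export
segmentAdhesions <- function(image, mask, config = segmentationConfig()) {
  m <- pixels(image)
  mk <- pixels(mask)
  if (!identical(dim(m), dim(mk)))
    faStop("ShapeMismatch", "image is %dx%d but mask is %dx%d",
           nrow(m), ncol(m), nrow(mk), ncol(mk))
  bgsub <- subtractBackground(image, config@rollingBallRadiusPx)
  ## threshold from the mask bounding box only
  idx <- which(mk, arr.ind = TRUE)
  rr <- range(idx[, 1]); cr <- range(idx[, 2])
  box <- pixels(bgsub)[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  thr <- autoThreshold(box, method = config@thresholdMethod,
                       fixedThreshold = config@fixedThreshold,
                       nLevels = 2L^bitDepth(image))
  binary <- pixels(bgsub) > if (is.na(thr$threshold)) Inf else thr$threshold
  lab <- if (config@watershedEnabled) {
    labelMatrix(watershedSplit(binary, config@smoothingSigmaPx,
                               config@hMaxima, config@connectivity))
  } else {
    labelComponents(binary, config@connectivity)
  }
  ## intersect with mask, keep label identity, renumber consecutively
  lab[!mk] <- 0L
  kept <- sort(unique(lab[lab > 0L]))
  relab <- integer(if (length(kept)) max(kept) else 0L)
  relab[kept] <- seq_along(kept)
  pos <- lab > 0L
  lab[pos] <- relab[lab[pos]]
  LabelMap(lab, metadata = list(
    threshold = thr$threshold,
    config = list(
      rollingBallRadiusPx = config@rollingBallRadiusPx,
      thresholdMethod = config@thresholdMethod,
      fixedThreshold = config@fixedThreshold,
      watershedEnabled = config@watershedEnabled,
      smoothingSigmaPx = config@smoothingSigmaPx,
      hMaxima = config@hMaxima,
      connectivity = config@connectivity)))
}
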