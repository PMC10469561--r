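## Core S4 containers: raster images, cell masks, adhesion label maps,
## FRAP intensity curves and one-phase-association fits.
## Raster convention throughout: matrices are indexed [row, col]; exported
## coordinates are 0-based with x = column and y = row, origin top-left.

#' Single-channel grayscale image
#'
#' An integer-valued 2-D raster of a focal-adhesion marker channel
#' (e.g. vinculin or paxillin staining), together with its bit depth and an
#' optional physical pixel size.
#'
#' @slot pixels Numeric matrix of non-negative integer-valued intensities,
#'   indexed \code{[row, col]}.
#' @slot bitDepth Integer, 8 or 16; all pixel values must lie in
#'   \code{[0, 2^bitDepth - 1]}.
#' @slot pixelSizeUm Physical pixel size in micrometers per pixel, or
#'   \code{NA} when unknown. A working range of 0.15-0.3 um/px is
#'   recommended for adhesion-scale morphometry.
#'
#' @seealso [loadImage()], [generateScene()]
#' @export
setClass("IntensityImage",
  representation(
    pixels = "matrix",
    bitDepth = "integer",
    pixelSizeUm = "numeric"
  ),
  prototype(bitDepth = 16L, pixelSizeUm = NA_real_)
)

setValidity("IntensityImage", function(object) {
  p <- object@pixels
  if (nrow(p) < 1L || ncol(p) < 1L)
    return("pixels must have height >= 1 and width >= 1")
  if (!object@bitDepth %in% c(8L, 16L))
    return("bitDepth must be 8 or 16")
  if (anyNA(p) || any(p < 0) || any(p > 2^object@bitDepth - 1))
    return(sprintf("pixel values must lie in [0, %d]", 2^object@bitDepth - 1))
  if (any(p != floor(p)))
    return("pixel values must be integer-valued")
  ps <- object@pixelSizeUm
  if (length(ps) != 1L || (!is.na(ps) && ps <= 0))
    return("pixelSizeUm must be a single positive value or NA")
  TRUE
})

#' Construct an IntensityImage
#'
#' @param pixels Numeric matrix of integer-valued intensities.
#' @param bitDepth 8 or 16.
#' @param pixelSizeUm Optional pixel size (um/px), \code{NA} if unknown.
#' @return An [IntensityImage-class] object.
#' @export
IntensityImage <- function(pixels, bitDepth = 16L, pixelSizeUm = NA_real_) {
  new("IntensityImage", pixels = pixels, bitDepth = as.integer(bitDepth),
      pixelSizeUm = as.numeric(pixelSizeUm))
}

#' Binary cell mask
#'
#' The footprint of one cell, drawn by the user (typically on the F-actin
#' channel) and supplied as an 8-bit binary image with foreground 255.
#' Derived geometry is precomputed: foreground area, centroid, the Euclidean
#' distance of every interior pixel to the nearest background pixel, and the
#' maximum of that distance map. The distance map drives the peripheral
#' adhesion classification.
#'
#' @slot pixels Logical matrix, \code{TRUE} = inside the cell.
#' @slot areaPx Number of foreground pixels.
#' @slot centroid Numeric (x, y), 0-based pixel coordinates of the
#'   foreground centroid.
#' @slot distanceMap Numeric matrix; Euclidean distance to the nearest
#'   background pixel, 0 on background.
#' @slot maxDistPx Maximum of \code{distanceMap}.
#'
#' @seealso [loadMask()], [classifyPeripheral()]
#' @export
setClass("CellMask",
  representation(
    pixels = "matrix",
    areaPx = "integer",
    centroid = "numeric",
    distanceMap = "matrix",
    maxDistPx = "numeric"
  )
)

setValidity("CellMask", function(object) {
  p <- object@pixels
  if (!is.logical(p)) return("pixels must be a logical matrix")
  if (object@areaPx < 1L) return("mask has no foreground pixel")
  if (object@areaPx != sum(p)) return("areaPx inconsistent with pixels")
  ctr <- object@centroid
  if (length(ctr) != 2L || ctr[1] < 0 || ctr[1] > ncol(p) - 1 ||
      ctr[2] < 0 || ctr[2] > nrow(p) - 1)
    return("centroid must lie within the raster bounds")
  if (!identical(dim(object@distanceMap), dim(p)))
    return("distanceMap dimensions must match pixels")
  if (any(object@distanceMap[!p] != 0))
    return("distanceMap must be 0 on background pixels")
  TRUE
})

#' Construct a CellMask from a binary matrix
#'
#' Computes the derived geometry (area, centroid, interior distance map).
#'
#' @param pixels Logical matrix (or 0/1 numeric) with at least one
#'   foreground pixel.
#' @return A [CellMask-class] object.
#' @export
CellMask <- function(pixels) {
  if (!is.logical(pixels)) {
    if (!all(pixels %in% c(0, 1)))
      stop("InvalidMask: mask matrix must be logical or 0/1")
    pixels <- pixels > 0
  }
  if (!any(pixels)) stop("EmptyMask: mask contains no foreground pixel")
  idx <- which(pixels, arr.ind = TRUE)
  ctr <- c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)
  dm <- euclideanDistMap(pixels)
  new("CellMask", pixels = pixels, areaPx = as.integer(sum(pixels)),
      centroid = ctr, distanceMap = dm, maxDistPx = max(dm))
}

#' Adhesion label map
#'
#' Integer raster identifying segmented adhesions: 0 is background, k > 0 is
#' the k-th adhesion. Labels are consecutive 1..nLabels. The \code{metadata}
#' list carries provenance from segmentation (chosen threshold, config echo).
#'
#' @slot labels Integer matrix.
#' @slot nLabels Number of distinct positive labels.
#' @slot metadata Named list of provenance values.
#'
#' @seealso [segmentAdhesions()], [measureAdhesions()]
#' @export
setClass("LabelMap",
  representation(
    labels = "matrix",
    nLabels = "integer",
    metadata = "list"
  ),
  prototype(metadata = list())
)

setValidity("LabelMap", function(object) {
  l <- object@labels
  if (anyNA(l) || any(l < 0) || any(l != floor(l)))
    return("labels must be non-negative integers")
  pos <- sort(unique(l[l > 0]))
  if (length(pos) != object@nLabels)
    return("nLabels inconsistent with labels")
  if (length(pos) && !identical(as.integer(pos), seq_len(object@nLabels)))
    return("labels must be consecutive integers 1..nLabels")
  TRUE
})

LabelMap <- function(labels, metadata = list()) {
  storage.mode(labels) <- "integer"
  new("LabelMap", labels = labels,
      nLabels = as.integer(length(unique(labels[labels > 0]))),
      metadata = metadata)
}

#' Segmentation configuration
#'
#' Tunable parameters of the adhesion segmentation pipeline. Defaults follow
#' common fluorescence particle-analysis practice: a rolling-ball radius
#' large relative to adhesion size (50 px), global Otsu thresholding, and
#' distance-transform watershed with mild smoothing and shallow-maximum
#' suppression.
#'
#' @slot rollingBallRadiusPx Background-subtraction structuring-element
#'   radius in pixels (> 0).
#' @slot thresholdMethod One of \code{"otsu"}, \code{"triangle"},
#'   \code{"fixed"}.
#' @slot fixedThreshold Integer threshold, required iff
#'   \code{thresholdMethod == "fixed"}.
#' @slot watershedEnabled Split touching adhesions by distance-transform
#'   watershed.
#' @slot smoothingSigmaPx Gaussian sigma applied to the distance map before
#'   seeding (px; 0 disables).
#' @slot hMaxima Suppress distance-map maxima shallower than this depth
#'   before flooding; larger values merge more, smaller values over-segment.
#' @slot connectivity Pixel connectivity for component labeling, 4 or 8.
#' @export
setClass("SegmentationConfig",
  representation(
    rollingBallRadiusPx = "numeric",
    thresholdMethod = "character",
    fixedThreshold = "numeric",
    watershedEnabled = "logical",
    smoothingSigmaPx = "numeric",
    hMaxima = "numeric",
    connectivity = "integer"
  )
)

setValidity("SegmentationConfig", function(object) {
  if (object@rollingBallRadiusPx <= 0)
    return("rollingBallRadiusPx must be > 0")
  if (!object@thresholdMethod %in% c("otsu", "triangle", "fixed"))
    return("thresholdMethod must be otsu, triangle or fixed")
  if (object@thresholdMethod == "fixed" && is.na(object@fixedThreshold))
    return("fixedThreshold is required when thresholdMethod is 'fixed'")
  if (object@smoothingSigmaPx < 0) return("smoothingSigmaPx must be >= 0")
  if (object@hMaxima < 0) return("hMaxima must be >= 0")
  if (!object@connectivity %in% c(4L, 8L))
    return("connectivity must be 4 or 8")
  TRUE
})

#' Construct a SegmentationConfig
#'
#' @param rollingBallRadiusPx Rolling-ball radius (px), default 50.
#' @param thresholdMethod "otsu" (default), "triangle" or "fixed".
#' @param fixedThreshold Threshold value when \code{thresholdMethod} is
#'   "fixed".
#' @param watershedEnabled Logical, default \code{TRUE}.
#' @param smoothingSigmaPx Distance-map smoothing sigma (px), default 1.
#' @param hMaxima Shallow-maximum suppression depth, default 1.
#' @param connectivity 4 or 8 (default 8).
#' @return A [SegmentationConfig-class] object.
#' @export
segmentationConfig <- function(rollingBallRadiusPx = 50,
                               thresholdMethod = c("otsu", "triangle", "fixed"),
                               fixedThreshold = NA_real_,
                               watershedEnabled = TRUE,
                               smoothingSigmaPx = 1.0,
                               hMaxima = 1.0,
                               connectivity = 8L) {
  new("SegmentationConfig",
      rollingBallRadiusPx = rollingBallRadiusPx,
      thresholdMethod = match.arg(thresholdMethod),
      fixedThreshold = as.numeric(fixedThreshold),
      watershedEnabled = isTRUE(watershedEnabled),
      smoothingSigmaPx = smoothingSigmaPx,
      hMaxima = hMaxima,
      connectivity = as.integer(connectivity))
}

#' FRAP intensity time series
#'
#' Mean ROI intensity over time for one region in a FRAP experiment, with
#' its role in the analysis and the number of pre-bleach frames. Times must
#' be strictly increasing. The standard acquisition records 2 pre-bleach
#' frames of the bleached ROI plus one background ROI, then a post-bleach
#' time lapse (e.g. every 15 s for 5 min).
#'
#' @slot times Acquisition times in seconds, strictly increasing.
#' @slot intensities ROI mean intensities (arbitrary units, or normalized).
#' @slot role One of \code{"bleached"}, \code{"reference"},
#'   \code{"background"}, \code{"normalized"}.
#' @slot nPre Number of pre-bleach frames (>= 1 for bleached/normalized).
#' @export
setClass("FRAPCurve",
  representation(
    times = "numeric",
    intensities = "numeric",
    role = "character",
    nPre = "integer"
  )
)

setValidity("FRAPCurve", function(object) {
  if (length(object@times) != length(object@intensities))
    return("times and intensities must have equal length")
  if (length(object@times) < 2L) return("curve needs at least 2 points")
  if (any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (!object@role %in% c("bleached", "reference", "background", "normalized"))
    return("role must be bleached, reference, background or normalized")
  if (object@role %in% c("bleached", "normalized") && object@nPre < 1L)
    return("bleached/normalized curves need nPre >= 1")
  TRUE
})

#' Construct a FRAPCurve
#'
#' @param times Seconds, strictly increasing.
#' @param intensities Intensities, same length as \code{times}.
#' @param role Curve role; see [FRAPCurve-class].
#' @param nPre Number of pre-bleach frames (default 2).
#' @return A [FRAPCurve-class] object.
#' @export
FRAPCurve <- function(times, intensities,
                      role = c("bleached", "reference", "background",
                               "normalized"),
                      nPre = 2L) {
  new("FRAPCurve", times = as.numeric(times),
      intensities = as.numeric(intensities),
      role = match.arg(role), nPre = as.integer(nPre))
}

#' One-phase association fit of a FRAP recovery
#'
#' Least-squares fit of F(t) = f0 + (plateau - f0)(1 - exp(-k t)) to the
#' post-bleach segment of a normalized recovery curve, with derived
#' half-time ln(2)/k and mobile fraction (plateau - f0)/(1 - f0).
#'
#' @slot k Recovery rate (per second), > 0.
#' @slot plateau Fitted asymptote on the normalized scale.
#' @slot f0 Fitted intensity immediately after the bleach.
#' @slot halfTimeS ln(2)/k, seconds.
#' @slot mobileFraction (plateau - f0)/(1 - f0); values slightly above 1 are
#'   reported with a warning, never clipped silently.
#' @slot residualSSE Sum of squared fit residuals.
#' @export
setClass("FRAPFit",
  representation(
    k = "numeric",
    plateau = "numeric",
    f0 = "numeric",
    halfTimeS = "numeric",
    mobileFraction = "numeric",
    residualSSE = "numeric"
  )
)

setValidity("FRAPFit", function(object) {
  if (object@k <= 0) return("k must be > 0")
  if (abs(object@halfTimeS * object@k - log(2)) > 1e-9)
    return("halfTimeS must equal ln(2)/k")
  TRUE
})

## ---- accessors ----

#' @rdname faquant-accessors
#' @export
setMethod("pixels", "IntensityImage", function(object) object@pixels)
#' @rdname faquant-accessors
#' @export
setMethod("pixels", "CellMask", function(object) object@pixels)
#' @rdname faquant-accessors
#' @export
setMethod("bitDepth", "IntensityImage", function(object) object@bitDepth)
#' @rdname faquant-accessors
#' @export
setMethod("pixelSizeUm", "IntensityImage", function(object) object@pixelSizeUm)
#' @rdname faquant-accessors
#' @export
setMethod("maskArea", "CellMask", function(object) object@areaPx)
#' @rdname faquant-accessors
#' @export
setMethod("maskCentroid", "CellMask", function(object) object@centroid)
#' @rdname faquant-accessors
#' @export
setMethod("distanceMap", "CellMask", function(object) object@distanceMap)
#' @rdname faquant-accessors
#' @export
setMethod("maxBorderDist", "CellMask", function(object) object@maxDistPx)
#' @rdname faquant-accessors
#' @export
setMethod("labelMatrix", "LabelMap", function(object) object@labels)
#' @rdname faquant-accessors
#' @export
setMethod("nLabels", "LabelMap", function(object) object@nLabels)
#' @rdname faquant-accessors
#' @export
setMethod("frapTimes", "FRAPCurve", function(object) object@times)
#' @rdname faquant-accessors
#' @export
setMethod("frapIntensities", "FRAPCurve", function(object) object@intensities)
#' @rdname faquant-accessors
#' @export
setMethod("frapRole", "FRAPCurve", function(object) object@role)
#' @rdname faquant-accessors
#' @export
setMethod("nPreBleach", "FRAPCurve", function(object) object@nPre)
#' @rdname faquant-accessors
#' @export
setMethod("recoveryRate", "FRAPFit", function(object) object@k)
#' @rdname faquant-accessors
#' @export
setMethod("halfTime", "FRAPFit", function(object) object@halfTimeS)
#' @rdname faquant-accessors
#' @export
setMethod("mobileFraction", "FRAPFit", function(object) object@mobileFraction)

## ---- show methods ----

setMethod("show", "IntensityImage", function(object) {
  cat(sprintf("IntensityImage: %d x %d, %d-bit, range [%g, %g]%s\n",
              nrow(object@pixels), ncol(object@pixels), object@bitDepth,
              min(object@pixels), max(object@pixels),
              if (is.na(object@pixelSizeUm)) ""
              else sprintf(", %.3g um/px", object@pixelSizeUm)))
})

setMethod("show", "CellMask", function(object) {
  cat(sprintf(
    "CellMask: %d x %d, area %d px, centroid (%.1f, %.1f), max border dist %.2f px\n",
    nrow(object@pixels), ncol(object@pixels), object@areaPx,
    object@centroid[1], object@centroid[2], object@maxDistPx))
})

setMethod("show", "LabelMap", function(object) {
  cat(sprintf("LabelMap: %d x %d, %d adhesions\n",
              nrow(object@labels), ncol(object@labels), object@nLabels))
  if (!is.null(object@metadata$threshold))
    cat(sprintf("  threshold: %g\n", object@metadata$threshold))
})

setMethod("show", "FRAPCurve", function(object) {
  cat(sprintf("FRAPCurve (%s): %d frames, t = [%g, %g] s, %d pre-bleach\n",
              object@role, length(object@times), min(object@times),
              max(object@times), object@nPre))
})

setMethod("show", "FRAPFit", function(object) {
  cat(sprintf(
    "FRAPFit: k = %.4g /s, half-time = %.4g s, mobile fraction = %.3f\n",
    object@k, object@halfTimeS, object@mobileFraction))
  cat(sprintf("  f0 = %.4g, plateau = %.4g, SSE = %.4g\n",
              object@f0, object@plateau, object@residualSSE))
})
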