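## Per-adhesion morphometrics and per-cell summaries. Coordinates are
## 0-based (x = column, y = row, y increases downward); angles are degrees
## in that frame. Area and perimeter are always reported in pixels.

## second central moments of a pixel set given 0-based (x, y) coordinates
centralMoments <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  list(x0 = mx, y0 = my,
       mu20 = mean((x - mx)^2),
       mu02 = mean((y - my)^2),
       mu11 = mean((x - mx) * (y - my)))
}

## orientation (deg, [-90, 90)) and aspect ratio from second moments;
## isotropic shapes (equal eigenvalues within 1e-9) get orientation 0
momentShape <- function(mom) {
  tr <- mom$mu20 + mom$mu02
  det <- mom$mu20 * mom$mu02 - mom$mu11^2
  disc <- sqrt(max((mom$mu20 - mom$mu02)^2 / 4 + mom$mu11^2, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (l1 - l2 < 1e-9) {
    theta <- 0
    ar <- 1
  } else {
    theta <- 0.5 * atan2(2 * mom$mu11, mom$mu20 - mom$mu02) * 180 / pi
    if (theta >= 90) theta <- theta - 180
    if (theta < -90) theta <- theta + 180
    ar <- if (l2 <= 1e-12) Inf else sqrt(l1 / l2)
  }
  list(orientation = theta, ar = ar, l1 = l1, l2 = l2)
}

## fold an angle difference into the acute range [0, 90]
foldAcute <- function(d) {
  d <- abs(d) %% 180
  ifelse(d > 90, 180 - d, d)
}

## measure one adhesion from its pixel rows/cols (1-based matrix indices)
measureRegion <- function(rows, cols, mask, nr, nc) {
  if (!length(rows)) faStop("EmptyRegion", "adhesion has no pixels")
  x <- cols - 1; y <- rows - 1
  mom <- centralMoments(x, y)
  shp <- momentShape(mom)
  bin <- matrix(FALSE, nr, nc)
  bin[cbind(rows, cols)] <- TRUE
  ## crop to bounding box (padded inside contourPerimeter)
  rrg <- range(rows); crg <- range(cols)
  per <- contourPerimeter(bin[rrg[1]:rrg[2], crg[1]:crg[2], drop = FALSE])
  area <- length(rows)
  ctr <- maskCentroid(mask)
  ## distance map sampled at the nearest-integer centroid pixel
  rc <- round(mom$y0) + 1
  cc <- round(mom$x0) + 1
  inMask <- rc >= 1 && rc <= nr && cc >= 1 && cc <= nc && pixels(mask)[rc, cc]
  dist <- if (inMask) distanceMap(mask)[rc, cc] else 0
  ang <- atan2(mom$y0 - ctr[["y"]], mom$x0 - ctr[["x"]]) * 180 / pi
  data.frame(
    fa_area_px = area,
    perim_px = per,
    x0_px = mom$x0,
    y0_px = mom$y0,
    orientation_deg = shp$orientation,
    ar = shp$ar,
    sf = per^2 / area,
    dist_px = dist,
    angle_deg = ang,
    rel_orientation_deg = foldAcute(shp$orientation - ang),
    centroid_outside_mask = !inMask)
}

#' Measure all adhesions in a label map
#'
#' Computes, for every labeled adhesion, the ten morphometric parameters:
#' pixel area, sub-pixel contour perimeter, centroid (x, y), orientation of
#' the moment-equivalent ellipse's major axis (degrees in [-90, 90)),
#' aspect ratio (major/minor axis), shape factor \eqn{sf = perimeter^2 /
#' area} (4\eqn{\pi} for a circle), centroid distance to the cell border,
#' angle of the centroid relative to the cell centroid, and the acute
#' relative orientation between the adhesion axis and that angle (0 deg =
#' radially aligned, 90 deg = perpendicular). Each adhesion is also
#' classified as peripheral when its border distance is less than
#' \code{periphFrac} of the mask's maximum interior distance. A
#' \code{centroid_outside_mask} flag marks adhesions whose rounded centroid
#' falls outside a concave mask (their \code{dist_px} is 0).
#'
#' @param labels A [LabelMap-class].
#' @param mask The [CellMask-class] the labels were segmented in.
#' @param periphFrac Peripheral-distance fraction (default 0.1).
#' @return A data.frame with one row per adhesion: \code{label}, the ten
#'   parameters, \code{is_peripheral}, \code{centroid_outside_mask}.
#' @export
measureAdhesions <- function(labels, mask, periphFrac = 0.1) {
  l <- labelMatrix(labels)
  n <- nLabels(labels)
  empty <- data.frame(
    label = integer(0), fa_area_px = integer(0), perim_px = numeric(0),
    x0_px = numeric(0), y0_px = numeric(0), orientation_deg = numeric(0),
    ar = numeric(0), sf = numeric(0), dist_px = numeric(0),
    angle_deg = numeric(0), rel_orientation_deg = numeric(0),
    is_peripheral = logical(0), centroid_outside_mask = logical(0))
  if (n == 0L) return(empty)
  idx <- which(l > 0L)
  byLab <- split(idx, l[idx])
  nr <- nrow(l); nc <- ncol(l)
  rows <- lapply(seq_len(n), function(k) {
    px <- byLab[[as.character(k)]]
    measureRegion(((px - 1L) %% nr) + 1L, ((px - 1L) %/% nr) + 1L,
                  mask, nr, nc)
  })
  out <- do.call(rbind, rows)
  out <- cbind(label = seq_len(n), out)
  out$is_peripheral <- classifyPeripheral(out$dist_px, maxBorderDist(mask),
                                          periphFrac)
  out[, c("label", FA_COLUMNS, "centroid_outside_mask")]
}

#' Peripheral adhesion classification
#'
#' An adhesion is peripheral when its centroid-to-border distance is
#' strictly less than \code{periphFrac} (default 10%) of the maximum
#' distance from the border to the interior of the cell mask. The
#' comparison is a strict \code{<}: an adhesion exactly at the cutoff is
#' not peripheral.
#'
#' @param distPx Centroid-to-border distance(s), pixels.
#' @param maxDistPx Maximum interior distance of the mask (> 0).
#' @param periphFrac Fraction in (0, 1), default 0.1.
#' @return Logical vector.
#' @examples
#' classifyPeripheral(c(5, 9.9, 10, 50), 100)  # TRUE TRUE FALSE FALSE
#' @export
classifyPeripheral <- function(distPx, maxDistPx, periphFrac = 0.1) {
  if (!is.numeric(periphFrac) || length(periphFrac) != 1L ||
      periphFrac <= 0 || periphFrac >= 1)
    faStop("InvalidFraction", "periphFrac must be in (0, 1)")
  if (maxDistPx <= 0) faStop("InvalidFraction", "maxDistPx must be > 0")
  distPx < periphFrac * maxDistPx
}

#' Filter adhesions by pixel area
#'
#' Keeps adhesions with \code{minAreaPx <= fa_area_px <= maxAreaPx},
#' preserving row order. Size exclusion removes unrealistically small
#' detections and under-segmented clusters that would otherwise be counted
#' as one large adhesion.
#'
#' @param records Data.frame from [measureAdhesions()].
#' @param minAreaPx Lower bound (default 1).
#' @param maxAreaPx Upper bound (default \code{Inf}).
#' @return The filtered data.frame.
#' @export
filterByArea <- function(records, minAreaPx = 1, maxAreaPx = Inf) {
  if (minAreaPx < 0 || maxAreaPx < 0 || minAreaPx > maxAreaPx)
    faStop("InvalidRange", "need 0 <= minAreaPx <= maxAreaPx")
  records[records$fa_area_px >= minAreaPx &
          records$fa_area_px <= maxAreaPx, , drop = FALSE]
}

#' Whole-cell summary of an adhesion measurement table
#'
#' One row of per-cell aggregates: mask area, adhesion count, the fraction
#' of the cell area covered by adhesions (exactly \eqn{\sum fa\_area\_px /
#' mask\_area\_px}), the fraction of peripheral adhesions, and the mean and
#' sample standard deviation (n - 1) of every numeric adhesion parameter.
#' With no adhesions the area fraction is 0 and the peripheral fraction is
#' \code{NA}.
#'
#' @param records Data.frame from [measureAdhesions()] (possibly filtered).
#' @param mask The [CellMask-class].
#' @return A one-row data.frame: \code{mask_area_px}, \code{no_fas},
#'   \code{area_fraction}, \code{frac_periph_fas}, then \code{mean_<p>} and
#'   \code{std_<p>} for each parameter.
#' @export
summarizeImage <- function(records, mask) {
  n <- nrow(records)
  out <- data.frame(
    mask_area_px = maskArea(mask),
    no_fas = n,
    area_fraction = if (n > 0) sum(records$fa_area_px) / maskArea(mask) else 0,
    frac_periph_fas = if (n > 0) sum(records$is_peripheral) / n else NA_real_)
  for (p in FA_NUMERIC) {
    out[[paste0("mean_", p)]] <- if (n > 0) mean(records[[p]]) else NA_real_
    out[[paste0("std_", p)]] <- if (n > 1) stats::sd(records[[p]]) else NA_real_
  }
  out
}

#' Annotate adhesion records with physical units
#'
#' Adds \code{fa_area_um2} and \code{perim_um} columns converted with the
#' physical pixel size. The pixel-unit columns are never altered, so tables
#' from images acquired at different magnifications stay comparable in
#' pixels. A message flags adhesions whose equivalent major-axis length
#' falls outside the 1-10 um range typical of focal adhesions.
#'
#' @param records Data.frame from [measureAdhesions()].
#' @param pixelSizeUm Pixel size in micrometers per pixel (> 0).
#' @return The records with two added columns.
#' @export
convertToPhysical <- function(records, pixelSizeUm) {
  if (!is.numeric(pixelSizeUm) || length(pixelSizeUm) != 1L ||
      is.na(pixelSizeUm) || pixelSizeUm <= 0)
    faStop("InvalidPixelSize", "pixelSizeUm must be a positive number")
  records$fa_area_um2 <- records$fa_area_px * pixelSizeUm^2
  records$perim_um <- records$perim_px * pixelSizeUm
  if (nrow(records)) {
    ## equivalent-ellipse major axis from area and aspect ratio
    majorUm <- 2 * sqrt(records$fa_area_px * records$ar / pi) * pixelSizeUm
    odd <- sum(is.finite(majorUm) & (majorUm < 1 | majorUm > 10))
    if (odd > 0)
      message(sprintf(
        "%d adhesion(s) have equivalent lengths outside the typical 1-10 um range",
        odd))
  }
  records
}
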