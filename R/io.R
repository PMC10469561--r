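## Reading and writing external artifacts: TIFF/PNG rasters, the
## "<stem>_mask" pairing convention, per-cell CSV outputs and combined
## tables. Area/perimeter columns are always pixels; coordinates written
## are 0-based with x = column, y = row.

#' @importFrom tools file_path_sans_ext file_ext
#' @importFrom utils write.csv read.csv packageVersion
NULL

FA_COLUMNS <- c("fa_area_px", "perim_px", "x0_px", "y0_px",
                "orientation_deg", "ar", "sf", "dist_px", "angle_deg",
                "rel_orientation_deg", "is_peripheral")
FA_NUMERIC <- setdiff(FA_COLUMNS, "is_peripheral")
IMAGE_EXTENSIONS <- c("tif", "tiff", "png")

## decode a raster file -> list(pixels, bitDepth); stops on multichannel,
## float or >16-bit input.
readRasterFile <- function(path) {
  if (!file.exists(path)) faStop("FileNotFound", "no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, as.is = TRUE, info = TRUE, all = FALSE)
    bits <- attr(arr, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
    if (length(dim(arr)) == 3L)
      faStop("UnsupportedImage",
             "%s has %d channels; split channels first and supply the adhesion channel only",
             path, dim(arr)[3])
    if (bits > 16L)
      faStop("UnsupportedImage", "%s: %d-bit images are not supported", path, bits)
    if (any(arr != floor(arr)))
      faStop("UnsupportedImage", "%s: floating-point TIFF not supported", path)
    list(pixels = matrix(as.numeric(arr), nrow(arr), ncol(arr)),
         bitDepth = if (bits <= 8L) 8L else 16L)
  } else if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    if (length(dim(arr)) == 3L)
      faStop("UnsupportedImage",
             "%s has %d channels; split channels first and supply the adhesion channel only",
             path, dim(arr)[3])
    if (bits > 16L)
      faStop("UnsupportedImage", "%s: %d-bit images are not supported", path, bits)
    scale <- 2^bits - 1
    list(pixels = matrix(round(as.numeric(arr) * scale), nrow(arr), ncol(arr)),
         bitDepth = if (bits <= 8L) 8L else 16L)
  } else {
    faStop("UnsupportedImage", "unsupported file type: %s", path)
  }
}

#' Load a single-channel adhesion image
#'
#' Reads an 8- or 16-bit single-channel grayscale TIFF or PNG. Multi-channel
#' images are rejected: split the merged channels first and pass only the
#' adhesion-marker channel.
#'
#' @param path Path to a .tif/.tiff/.png file.
#' @param pixelSizeUm Optional physical pixel size (um/px) to attach.
#' @return An [IntensityImage-class].
#' @examples
#' tf <- tempfile(fileext = ".tif")
#' tiff::writeTIFF(matrix(runif(64), 8, 8), tf, bits.per.sample = 16)
#' img <- loadImage(tf)
#' bitDepth(img)
#' @export
loadImage <- function(path, pixelSizeUm = NA_real_) {
  r <- readRasterFile(path)
  IntensityImage(r$pixels, bitDepth = r$bitDepth, pixelSizeUm = pixelSizeUm)
}

#' Load a binary cell mask
#'
#' Reads an 8-bit binary mask image in which every pixel is 0 or 255
#' (foreground = 255, i.e. white cell on black background), and precomputes
#' the mask geometry used downstream.
#'
#' @param path Path to the mask image file.
#' @return A [CellMask-class].
#' @export
loadMask <- function(path) {
  r <- readRasterFile(path)
  vals <- unique(as.vector(r$pixels))
  if (!all(vals %in% c(0, 255)))
    faStop("InvalidMask",
           "%s: mask pixels must all be 0 or 255 (found values %s)",
           path, paste(utils::head(sort(setdiff(vals, c(0, 255))), 5),
                       collapse = ", "))
  if (!any(r$pixels == 255))
    faStop("EmptyMask", "%s: mask has no foreground (255) pixel", path)
  CellMask(r$pixels == 255)
}

#' Discover image/mask pairs in a directory
#'
#' Pairs every non-mask image \code{<stem>.<ext>} with its companion
#' \code{<stem>_mask.<ext2>} (extensions may differ among tif/tiff/png).
#' Images without a mask and orphan masks produce warnings and are excluded.
#' The result is sorted by stem and depends only on the set of files
#' present, not on listing order.
#'
#' @param directory Directory containing the images.
#' @param maskSuffix Mask naming suffix (default \code{"_mask"}).
#' @param extensions Accepted file extensions.
#' @return A data.frame with columns \code{stem}, \code{image_path},
#'   \code{mask_path}, sorted by stem.
#' @export
findImageMaskPairs <- function(directory, maskSuffix = "_mask",
                               extensions = IMAGE_EXTENSIONS) {
  if (!dir.exists(directory))
    faStop("NotADirectory", "%s is not a directory", directory)
  files <- sort(list.files(directory,
    pattern = paste0("\\.(", paste(extensions, collapse = "|"), ")$"),
    ignore.case = TRUE))
  stems <- tools::file_path_sans_ext(files)
  isMask <- endsWith(stems, maskSuffix)
  imgFiles <- files[!isMask]
  imgStems <- stems[!isMask]
  maskFiles <- files[isMask]
  maskStems <- substr(stems[isMask], 1L,
                      nchar(stems[isMask]) - nchar(maskSuffix))
  mi <- match(imgStems, maskStems)
  unmatched <- imgFiles[is.na(mi)]
  if (length(unmatched))
    warning(sprintf("no %s image for: %s", maskSuffix,
                    paste(unmatched, collapse = ", ")), call. = FALSE)
  orphan <- maskFiles[!maskStems %in% imgStems]
  if (length(orphan))
    warning(sprintf("orphan mask image(s): %s",
                    paste(orphan, collapse = ", ")), call. = FALSE)
  keep <- !is.na(mi)
  out <- data.frame(
    stem = imgStems[keep],
    image_path = file.path(directory, imgFiles[keep]),
    mask_path = file.path(directory, maskFiles[mi[keep]]),
    stringsAsFactors = FALSE)
  out[order(out$stem), , drop = FALSE]
}

## deterministic distinct label colors: golden-angle hue walk
labelColors <- function(n) {
  if (n == 0L) return(character(0))
  k <- seq_len(n)
  grDevices::hsv(h = (k * 0.618033988749895) %% 1,
                 s = 0.55 + 0.4 * ((k * 7L) %% 3L) / 2,
                 v = 0.75 + 0.25 * ((k * 5L) %% 2L))
}

## write an RGB overlay PNG of the label map, background black
writeOverlay <- function(labels, path) {
  l <- labelMatrix(labels)
  n <- nLabels(labels)
  cols <- grDevices::col2rgb(labelColors(n)) / 255
  arr <- array(0, dim = c(nrow(l), ncol(l), 3L))
  if (n > 0L) {
    idx <- which(l > 0)
    for (ch in 1:3) {
      plane <- arr[, , ch]
      plane[idx] <- cols[ch, l[idx]]
      arr[, , ch] <- plane
    }
  }
  png::writePNG(arr, path)
  invisible(path)
}

## round numeric columns to 6 significant digits, write deterministically
writeCsv6 <- function(df, path) {
  for (j in seq_along(df)) df[[j]] <- signif6(df[[j]])
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) faStop("WriteError", "cannot write %s", path)
  invisible(path)
}

#' Write per-image analysis outputs
#'
#' Creates \code{outRoot/<stem>/} holding \code{"FA data.csv"} (one row per
#' adhesion), \code{"image data.csv"} (one row of whole-cell values), and a
#' color-coded label overlay \code{<stem>_labels.png}. Names with spaces
#' match the original macro's output layout; set \code{underscoreNames} for
#' shell-friendly names.
#'
#' @param stem Image stem (output directory name).
#' @param records Per-adhesion data.frame from [measureAdhesions()].
#' @param summary One-row data.frame from [summarizeImage()].
#' @param labels [LabelMap-class] for the overlay.
#' @param outRoot Output root directory.
#' @param underscoreNames Use \code{FA_data.csv}/\code{image_data.csv}.
#' @return Invisibly, the written file paths.
#' @export
writeOutputs <- function(stem, records, summary, labels, outRoot,
                         underscoreNames = FALSE) {
  dir <- file.path(outRoot, stem)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    faStop("WriteError", "cannot create %s", dir)
  faName <- if (underscoreNames) "FA_data.csv" else "FA data.csv"
  imName <- if (underscoreNames) "image_data.csv" else "image data.csv"
  faPath <- file.path(dir, faName)
  imPath <- file.path(dir, imName)
  ovPath <- file.path(dir, paste0(stem, "_labels.png"))
  writeCsv6(records[, FA_COLUMNS, drop = FALSE], faPath)
  writeCsv6(summary, imPath)
  writeOverlay(labels, ovPath)
  invisible(c(faPath, imPath, ovPath))
}

#' Write combined tables across all analyzed images
#'
#' Collects every per-adhesion row and every per-image row into two CSVs
#' written to the input directory itself, each row prefixed with the source
#' image stem. Row order is image order, then label order.
#'
#' @param allRecords Named list of per-adhesion data.frames (names = stems).
#' @param allSummaries Named list of one-row image summaries.
#' @param directory Destination directory.
#' @param underscoreNames Use underscore file names.
#' @return Invisibly, the written file paths.
#' @export
writeCombinedTables <- function(allRecords, allSummaries, directory,
                                underscoreNames = FALSE) {
  if (!length(allSummaries))
    faStop("WriteError", "no analyzed images to combine")
  faName <- if (underscoreNames) "combined_FA_data.csv"
            else "combined FA data.csv"
  imName <- if (underscoreNames) "combined_image_data.csv"
            else "combined image data.csv"
  recs <- do.call(rbind, lapply(names(allRecords), function(s) {
    df <- allRecords[[s]][, FA_COLUMNS, drop = FALSE]
    if (nrow(df)) cbind(image = s, df, stringsAsFactors = FALSE)
    else cbind(image = character(0), df)
  }))
  sums <- do.call(rbind, lapply(names(allSummaries), function(s)
    cbind(image = s, allSummaries[[s]], stringsAsFactors = FALSE)))
  faPath <- file.path(directory, faName)
  imPath <- file.path(directory, imName)
  writeCsv6(recs, faPath)
  writeCsv6(sums, imPath)
  invisible(c(faPath, imPath))
}

## write an IntensityImage (or plain matrix) as a TIFF at a given bit depth
writeImageFile <- function(pixels, path, bitDepth = 16L) {
  if (is(pixels, "IntensityImage")) {
    bitDepth <- bitDepth(pixels)
    pixels <- pixels(pixels)
  }
  tiff::writeTIFF(pixels / (2^bitDepth - 1), path,
                  bits.per.sample = as.integer(bitDepth))
  invisible(path)
}
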