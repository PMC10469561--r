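## Directory-driven workflows behind the command-line entry points:
## analyze a folder of image/mask pairs, emit a synthetic scene, fit a
## FRAP table. Every behavior here is a thin composition of the exported
## library functions.

#' Analyze a directory of adhesion images
#'
#' Discovers all \code{<stem>}/\code{<stem>_mask} image pairs, and for each
#' pair segments the adhesions, applies the area filter, measures the
#' morphometric parameters, summarizes the cell, and writes the per-image
#' outputs. Combined tables across all images and a run log (package
#' version, configuration, per-image threshold and counts) are written at
#' the end. A failing image is recorded and skipped; the remaining images
#' are still processed, and the returned status is non-zero if anything
#' failed.
#'
#' @param inputDir Directory with the image/mask pairs.
#' @param outRoot Output root (default: \code{inputDir}).
#' @param config [SegmentationConfig-class] (default
#'   [segmentationConfig()]).
#' @param periphFrac Peripheral-distance fraction, default 0.1.
#' @param minAreaPx,maxAreaPx Adhesion size filter (defaults keep all).
#' @param pixelSizeUm Optional pixel size; when given, physical-unit
#'   columns are appended to the per-image tables.
#' @param underscoreNames Use underscore CSV names.
#' @param verbose Print per-image progress.
#' @return Invisibly, a list: \code{records} and \code{summaries} (named by
#'   stem), \code{failures} (named character vector of error messages),
#'   \code{status} (0 = all images analyzed).
#' @export
analyzeDirectory <- function(inputDir, outRoot = inputDir,
                             config = segmentationConfig(),
                             periphFrac = 0.1, minAreaPx = 1,
                             maxAreaPx = Inf, pixelSizeUm = NULL,
                             underscoreNames = FALSE, verbose = TRUE) {
  pairs <- findImageMaskPairs(inputDir)
  if (!nrow(pairs))
    faStop("NoPairsFound", "no image/mask pairs in %s", inputDir)
  if (!dir.exists(outRoot)) dir.create(outRoot, recursive = TRUE)
  records <- list(); summaries <- list(); failures <- character(0)
  thresholds <- numeric(0)
  for (i in seq_len(nrow(pairs))) {
    stem <- pairs$stem[i]
    res <- tryCatch({
      img <- loadImage(pairs$image_path[i],
                       pixelSizeUm = if (is.null(pixelSizeUm)) NA_real_
                                     else pixelSizeUm)
      msk <- loadMask(pairs$mask_path[i])
      seg <- segmentAdhesions(img, msk, config)
      recs <- measureAdhesions(seg, msk, periphFrac = periphFrac)
      recs <- filterByArea(recs, minAreaPx, maxAreaPx)
      if (!is.null(pixelSizeUm))
        recs <- convertToPhysical(recs, pixelSizeUm)
      summ <- summarizeImage(recs, msk)
      writeOutputs(stem, recs, summ, seg, outRoot,
                   underscoreNames = underscoreNames)
      list(recs = recs, summ = summ,
           threshold = seg@metadata$threshold)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[stem] <- conditionMessage(res)
      if (verbose) message(sprintf("FAILED %s: %s", stem, failures[stem]))
    } else {
      records[[stem]] <- res$recs
      summaries[[stem]] <- res$summ
      thresholds[stem] <- if (is.null(res$threshold)) NA_real_
                          else res$threshold
      if (verbose)
        message(sprintf("%s: %d adhesions (threshold %g)", stem,
                        nrow(res$recs), thresholds[stem]))
    }
  }
  if (length(summaries))
    writeCombinedTables(records, summaries, outRoot,
                        underscoreNames = underscoreNames)
  writeRunLog(file.path(outRoot, "faquant_run_log.txt"), config, periphFrac,
              minAreaPx, maxAreaPx, pixelSizeUm, thresholds, records,
              failures)
  invisible(list(records = records, summaries = summaries,
                 failures = failures,
                 status = if (length(failures)) 1L else 0L))
}

writeRunLog <- function(path, config, periphFrac, minAreaPx, maxAreaPx,
                        pixelSizeUm, thresholds, records, failures) {
  lines <- c(
    sprintf("faquant %s", as.character(utils::packageVersion("faquant"))),
    sprintf("rollingBallRadiusPx=%g thresholdMethod=%s fixedThreshold=%s",
            config@rollingBallRadiusPx, config@thresholdMethod,
            config@fixedThreshold),
    sprintf("watershedEnabled=%s smoothingSigmaPx=%g hMaxima=%g connectivity=%d",
            config@watershedEnabled, config@smoothingSigmaPx,
            config@hMaxima, config@connectivity),
    sprintf("periphFrac=%g minAreaPx=%g maxAreaPx=%g pixelSizeUm=%s",
            periphFrac, minAreaPx, maxAreaPx,
            if (is.null(pixelSizeUm)) "NA" else pixelSizeUm),
    vapply(names(thresholds), function(s)
      sprintf("image=%s threshold=%g n_fas=%d", s, thresholds[s],
              nrow(records[[s]])), character(1)),
    vapply(names(failures), function(s)
      sprintf("FAILED image=%s error=%s", s, failures[s]), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic scene to disk
#'
#' Generates a ground-truth scene and writes \code{<stem>.tif},
#' \code{<stem>_mask.tif} and \code{<stem>_truth.csv} into a directory that
#' [analyzeDirectory()] can consume directly. Prints the realized
#' signal-to-noise ratio.
#'
#' @param outDir Output directory (created if needed).
#' @param config A [sceneConfig()].
#' @param stem File stem, default \code{"scene1"}.
#' @return Invisibly, the scene list from [generateScene()] plus the
#'   written paths.
#' @export
simulateScene <- function(outDir, config = sceneConfig(), stem = "scene1") {
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    faStop("WriteError", "cannot create %s", outDir)
  sc <- generateScene(config)
  imgPath <- file.path(outDir, paste0(stem, ".tif"))
  maskPath <- file.path(outDir, paste0(stem, "_mask.tif"))
  truthPath <- file.path(outDir, paste0(stem, "_truth.csv"))
  writeImageFile(sc$image, imgPath)
  writeImageFile(matrix(as.numeric(pixels(sc$mask)) * 255,
                        nrow(pixels(sc$mask)), ncol(pixels(sc$mask))),
                 maskPath, bitDepth = 8L)
  writeCsv6(sc$truth, truthPath)
  message(sprintf("scene '%s': %d adhesions, realized SNR %.1f", stem,
                  nrow(sc$truth), sc$snr))
  invisible(c(sc, list(paths = c(image = imgPath, mask = maskPath,
                                 truth = truthPath))))
}

#' Fit FRAP curves from a ROI table
#'
#' Reads a \code{time_s} + per-ROI CSV, normalizes every bleached ROI
#' (background subtraction, optional bleaching correction, pre-bleach
#' normalization), fits the one-phase association model per ROI and — when
#' two or more bleached ROIs are present — on their average, and writes the
#' normalized curves and a fit summary.
#'
#' @param path Input CSV.
#' @param bleached Bleached-ROI column names.
#' @param reference Optional reference column name (omit when no
#'   acquisition bleaching was observed).
#' @param background Optional background column name.
#' @param nPre Pre-bleach frame count, default 2.
#' @param outDir Output directory (default: the input file's directory).
#' @param underscoreNames Use underscore CSV names.
#' @return Invisibly, a list: \code{fits} (per-ROI [FRAPFit-class] or
#'   error message), \code{average} (fit or NULL), \code{normalized}
#'   (data.frame of the normalized curves).
#' @export
frapFitFile <- function(path, bleached, reference = NULL, background = NULL,
                        nPre = 2L, outDir = dirname(path),
                        underscoreNames = FALSE) {
  tab <- readFrapTable(path, bleached, reference, background, nPre)
  normalized <- lapply(tab$bleached, function(cv)
    normalizeFrap(cv, background = tab$background,
                  reference = tab$reference))
  fits <- lapply(normalized, function(cv)
    tryCatch(fitOnePhase(cv), error = function(e) conditionMessage(e)))
  avg <- if (length(normalized) >= 2L) averageAndFit(normalized) else NULL

  normDf <- data.frame(time_s = frapTimes(normalized[[1L]]))
  for (nm in names(normalized)) normDf[[nm]] <- frapIntensities(normalized[[nm]])
  fitRow <- function(name, fit) {
    if (is(fit, "FRAPFit"))
      data.frame(roi = name, k_per_s = fit@k, half_time_s = fit@halfTimeS,
                 mobile_fraction = fit@mobileFraction, f0 = fit@f0,
                 plateau = fit@plateau, residual_sse = fit@residualSSE,
                 error = "")
    else
      data.frame(roi = name, k_per_s = NA, half_time_s = NA,
                 mobile_fraction = NA, f0 = NA, plateau = NA,
                 residual_sse = NA, error = as.character(fit))
  }
  summDf <- do.call(rbind, c(
    lapply(names(fits), function(nm) fitRow(nm, fits[[nm]])),
    if (!is.null(avg)) list(fitRow("average", avg$average))))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  curvesName <- if (underscoreNames) "normalized_curves.csv"
                else "normalized curves.csv"
  fitsName <- if (underscoreNames) "frap_fits.csv" else "frap fits.csv"
  writeCsv6(normDf, file.path(outDir, curvesName))
  writeCsv6(summDf, file.path(outDir, fitsName))
  invisible(list(fits = fits, average = avg, normalized = normDf,
                 summary = summDf))
}
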