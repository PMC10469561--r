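## FRAP analysis: background subtraction, acquisition-bleaching correction,
## pre-bleach normalization and one-phase-association fitting.

#' @importFrom minpack.lm nlsLM
#' @importFrom stats approx coef
NULL

## resample a curve (or accept a scalar) onto a target time grid
resampleOnto <- function(curve, times) {
  if (is.numeric(curve) && length(curve) == 1L)
    return(rep(curve, length(times)))
  ct <- frapTimes(curve)
  if (max(ct) < min(times) || min(ct) > max(times))
    faStop("NonOverlappingTimes",
           "curve time range [%g, %g] does not overlap [%g, %g]",
           min(ct), max(ct), min(times), max(times))
  stats::approx(ct, frapIntensities(curve), xout = times, rule = 2)$y
}

#' Detect the bleach frame
#'
#' Finds the first frame whose intensity drops by more than half of the
#' running pre-bleach mean relative to the previous frame, and returns the
#' number of frames before it. Falls back to the curve's stored
#' \code{nPre} when no such drop exists.
#'
#' @param curve A [FRAPCurve-class].
#' @return Integer count of pre-bleach frames.
#' @export
detectBleachFrame <- function(curve) {
  I <- frapIntensities(curve)
  for (i in 2:length(I)) {
    if (I[i] < I[i - 1] - 0.5 * mean(I[1:(i - 1)]))
      return(i - 1L)
  }
  nPreBleach(curve)
}

#' Normalize a FRAP curve
#'
#' Standard FRAP normalization: (1) subtract the background ROI; (2) if a
#' reference ROI is supplied, divide by its background-subtracted intensity
#' relative to its own pre-bleach mean, which compensates the fluorescence
#' lost to acquisition bleaching (omit the reference when no such loss is
#' observed); (3) divide by the mean of the curve's pre-bleach frames, so
#' the pre-bleach level is exactly 1. Background and reference curves are
#' resampled onto the bleached time grid by linear interpolation when their
#' grids differ.
#'
#' @param bleached Bleached-ROI [FRAPCurve-class].
#' @param background Background ROI ([FRAPCurve-class]) or a constant;
#'   default 0.
#' @param reference Optional reference ROI for bleaching correction.
#' @return A [FRAPCurve-class] with role \code{"normalized"}.
#' @export
normalizeFrap <- function(bleached, background = 0, reference = NULL) {
  times <- frapTimes(bleached)
  nPre <- nPreBleach(bleached)
  bg <- resampleOnto(background, times)
  I1 <- frapIntensities(bleached) - bg
  if (!is.null(reference)) {
    ref <- resampleOnto(reference, times) - bg
    preRef <- mean(ref[seq_len(nPre)])
    if (preRef <= 0)
      faStop("ZeroPreBleach", "reference pre-bleach mean <= 0 after background subtraction")
    I1 <- I1 / (ref / preRef)
  }
  preMean <- mean(I1[seq_len(nPre)])
  if (preMean <= 0)
    faStop("ZeroPreBleach", "pre-bleach mean <= 0 after background subtraction")
  FRAPCurve(times, I1 / preMean, role = "normalized", nPre = nPre)
}

#' Fit a one-phase association recovery
#'
#' Unweighted least-squares fit of \eqn{F(t) = f_0 + (plateau - f_0)(1 -
#' e^{-kt})} to the post-bleach segment of a normalized curve, with time
#' re-zeroed at the first post-bleach frame. Initial values: \eqn{f_0} =
#' first post-bleach value, plateau = mean of the last 3 points, k = ln 2
#' over the time to half recovery. Reported alongside the parameters are
#' the half-time ln(2)/k and the mobile fraction (plateau - f0)/(1 - f0);
#' mobile fractions above 1 are flagged with a warning, never clipped.
#'
#' @param curve A normalized [FRAPCurve-class].
#' @param nPre Override the number of pre-bleach frames (default: the
#'   curve's own).
#' @return A [FRAPFit-class].
#' @examples
#' cv <- generateFrapCurves(k = 0.02, f0 = 0.2, plateau = 0.8)
#' fit <- fitOnePhase(normalizeFrap(cv$bleached, cv$background))
#' halfTime(fit)        # ln(2)/0.02 = 34.66 s
#' mobileFraction(fit)  # (0.8 - 0.2)/(1 - 0.2) = 0.75
#' @export
fitOnePhase <- function(curve, nPre = NULL) {
  if (is.null(nPre)) nPre <- nPreBleach(curve)
  times <- frapTimes(curve)
  I <- frapIntensities(curve)
  post <- seq.int(nPre + 1L, length(I))
  if (length(post) < 5L)
    faStop("InsufficientData", "need >= 5 post-bleach points, have %d",
           length(post))
  t <- times[post] - times[post][1L]
  y <- I[post]
  f0g <- y[1L]
  platg <- mean(utils::tail(y, 3L))
  noiseFloor <- max(2 * stats::sd(utils::tail(y, 3L)), 1e-8)
  if (!is.finite(platg) || platg <= f0g + noiseFloor)
    faStop("NoRecovery",
           "no detectable recovery (plateau %.4g <= f0 %.4g + noise floor)",
           platg, f0g)
  iHalf <- which(y >= f0g + 0.5 * (platg - f0g))
  tHalf <- if (length(iHalf) && t[iHalf[1L]] > 0) t[iHalf[1L]]
           else stats::median(t[t > 0])
  kg <- log(2) / tHalf
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ f0 + (plateau - f0) * (1 - exp(-k * t)),
      start = list(f0 = f0g, plateau = platg, k = kg),
      lower = c(f0 = -Inf, plateau = -Inf, k = 1e-10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      faStop("FitDiverged", "one-phase fit failed: %s", conditionMessage(e)))
  p <- stats::coef(fit)
  mob <- (p[["plateau"]] - p[["f0"]]) / (1 - p[["f0"]])
  if (is.finite(mob) && mob > 1 + 1e-6)
    warning(sprintf("mobile fraction %.3f exceeds 1", mob), call. = FALSE)
  new("FRAPFit", k = p[["k"]], plateau = p[["plateau"]], f0 = p[["f0"]],
      halfTimeS = log(2) / p[["k"]], mobileFraction = mob,
      residualSSE = sum(stats::resid(fit)^2))
}

#' Average normalized curves and fit
#'
#' Pointwise mean of two or more normalized curves on a common time grid,
#' followed by a one-phase association fit of the average. Combining ROIs
#' from independent experiments before fitting is the recommended practice;
#' the individual per-curve fits are returned alongside for dispersion
#' reporting (a curve whose own fit fails contributes \code{NULL}).
#'
#' @param curves List of >= 2 normalized [FRAPCurve-class] objects sharing
#'   one time grid and pre-bleach count.
#' @return A list: \code{average} ([FRAPFit-class]), \code{perCurve} (list
#'   of per-curve fits), \code{meanCurve} (the averaged
#'   [FRAPCurve-class]).
#' @export
averageAndFit <- function(curves) {
  if (!is.list(curves) || length(curves) < 2L)
    faStop("InsufficientCurves", "need >= 2 curves, have %d",
           if (is.list(curves)) length(curves) else 1L)
  t0 <- frapTimes(curves[[1L]])
  n0 <- nPreBleach(curves[[1L]])
  for (cv in curves[-1L]) {
    if (length(frapTimes(cv)) != length(t0) ||
        max(abs(frapTimes(cv) - t0)) > 1e-8 || nPreBleach(cv) != n0)
      faStop("GridMismatch", "curves must share one time grid and nPre")
  }
  meanI <- rowMeans(vapply(curves, frapIntensities, numeric(length(t0))))
  meanCurve <- FRAPCurve(t0, meanI, role = "normalized", nPre = n0)
  perCurve <- lapply(curves, function(cv)
    tryCatch(fitOnePhase(cv), error = function(e) NULL))
  list(average = fitOnePhase(meanCurve), perCurve = perCurve,
       meanCurve = meanCurve)
}

#' Read a FRAP ROI table
#'
#' Reads a CSV with a \code{time_s} column and one intensity column per
#' ROI, assigning each named column its role.
#'
#' @param path CSV path.
#' @param bleached Character vector of bleached-ROI column names.
#' @param reference Optional reference-ROI column name.
#' @param background Optional background-ROI column name.
#' @param nPre Pre-bleach frame count (default 2); set to \code{NA} to
#'   auto-detect per bleached curve from the intensity drop.
#' @return Named list: \code{bleached} (list of curves), \code{reference}
#'   (curve or NULL), \code{background} (curve or 0).
#' @export
readFrapTable <- function(path, bleached, reference = NULL,
                          background = NULL, nPre = 2L) {
  if (!file.exists(path)) faStop("FileNotFound", "no such file: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df))
    faStop("InvalidTable", "%s must contain a 'time_s' column", path)
  for (col in c(bleached, reference, background)) {
    if (!col %in% names(df))
      faStop("InvalidTable", "column '%s' not found in %s", col, path)
  }
  mk <- function(col, role, np) FRAPCurve(df$time_s, df[[col]], role = role,
                                          nPre = np)
  bl <- lapply(bleached, function(col) {
    cv <- mk(col, "bleached", if (is.na(nPre)) 1L else as.integer(nPre))
    if (is.na(nPre)) cv@nPre <- detectBleachFrame(cv)
    cv
  })
  names(bl) <- bleached
  list(bleached = bl,
       reference = if (!is.null(reference)) mk(reference, "reference", 1L),
       background = if (!is.null(background)) mk(background, "background", 1L)
                    else 0)
}
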