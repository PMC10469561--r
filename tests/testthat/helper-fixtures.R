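## Shared fixtures and independent oracles, all built in code.

## rasterize a disc as a 0/1 matrix
makeDisc <- function(r, n = 2 * r + 20, center = c(n / 2, n / 2)) {
  rw <- matrix(seq_len(n), n, n)
  cl <- matrix(seq_len(n), n, n, byrow = TRUE)
  matrix(as.numeric(sqrt((rw - center[1])^2 + (cl - center[2])^2) <= r), n, n)
}

## union of discs given (row, col, r) rows
makeDiscs <- function(spec, nr, nc) {
  rw <- matrix(seq_len(nr), nr, nc)
  cl <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(spec)))
    out <- out | (sqrt((rw - spec[i, 1])^2 + (cl - spec[i, 2])^2) <= spec[i, 3])
  matrix(as.numeric(out), nr, nc)
}

## brute-force oracle: area, centroid (0-based x/y) and central moments by
## direct per-pixel accumulation
bruteRegionStats <- function(binary) {
  idx <- which(binary > 0, arr.ind = TRUE)
  x <- idx[, 2] - 1
  y <- idx[, 1] - 1
  list(area = nrow(idx), x0 = mean(x), y0 = mean(y),
       mu20 = mean((x - mean(x))^2), mu02 = mean((y - mean(y))^2),
       mu11 = mean((x - mean(x)) * (y - mean(y))))
}

## exhaustive Otsu oracle: scan every candidate threshold, maximize
## between-class variance computed from first principles, ties -> lowest
bruteOtsu <- function(values, nLevels) {
  best <- -Inf; bestT <- 0L
  total <- length(values)
  for (t in 0:(nLevels - 2L)) {
    lo <- values[values <= t]
    hi <- values[values > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / total
    s <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (s > best + 1e-12) { best <- s; bestT <- t }
  }
  bestT
}

## random blob: union of a few random discs, guaranteed non-empty
randomBlob <- function(n = 40) {
  k <- sample(1:4, 1)
  spec <- cbind(sample(8:(n - 8), k, replace = TRUE),
                sample(8:(n - 8), k, replace = TRUE),
                sample(2:6, k, replace = TRUE))
  makeDiscs(spec, n, n)
}

## full-frame CellMask (all foreground) for measurement tests that need a
## mask but exercise shape statistics only
fullMask <- function(nr, nc = nr) CellMask(matrix(TRUE, nr, nc))

## write a matrix as TIFF at given bit depth
writeTiff <- function(m, path, bits = 16L) {
  tiff::writeTIFF(m / (2^bits - 1), path, bits.per.sample = as.integer(bits))
  path
}

## tiny well-separated scene for fast pipeline tests
smallSceneConfig <- function(seed = 1, nFAs = 8) {
  sceneConfig(imageSize = c(200L, 200L), cellRadiusPx = 80, nFAs = nFAs,
              areaLogMean = log(120), areaLogSd = 0.25, seed = seed)
}
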