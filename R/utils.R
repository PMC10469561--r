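## Shared raster primitives. All functions operate on plain [row, col]
## matrices; EBImage kernels used here are isotropic, so the transpose
## convention of EBImage's Image class is immaterial.

#' @importFrom EBImage distmap gblur opening makeBrush watershed
#' @importFrom igraph graph_from_edgelist components make_empty_graph add_vertices
NULL

## Euclidean distance to the nearest background pixel; 0 on background.
euclideanDistMap <- function(binary) {
  m <- matrix(as.numeric(binary), nrow(binary), ncol(binary))
  as.matrix(EBImage::distmap(m, metric = "euclidean"))
}

## Gaussian blur with reflective-safe zero padding (EBImage::gblur clips at
## image borders; padding keeps small rasters and border objects exact).
blurPadded <- function(m, sigma) {
  if (sigma <= 0) return(m)
  pad <- ceiling(4 * sigma)
  big <- matrix(0, nrow(m) + 2 * pad, ncol(m) + 2 * pad)
  big[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  sm <- as.matrix(EBImage::gblur(big, sigma = sigma))
  sm[pad + seq_len(nrow(m)), pad + seq_len(ncol(m)), drop = FALSE]
}

#' Connected-component labeling
#'
#' Labels connected foreground components of a binary raster at 4- or
#' 8-connectivity. Labels are consecutive integers assigned in order of each
#' component's first pixel in column-major scan order, so the output is a
#' pure function of the input.
#'
#' @param binary Logical (or 0/1) matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of labels, 0 = background.
#' @export
labelComponents <- function(binary, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  fg <- binary > 0
  nr <- nrow(fg); nc <- ncol(fg)
  out <- matrix(0L, nr, nc)
  idx <- which(fg)
  if (!length(idx)) return(out)
  ## map raster index -> vertex id
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  offs <- list(c(1L, 0L), c(0L, 1L))                 # down, right
  if (connectivity == 8L)
    offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))     # down-right, up-right
  edges <- NULL
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  for (o in offs) {
    r2 <- r + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- fg[j]
    if (any(keep))
      edges <- rbind(edges, cbind(vid[idx[ok][keep]], vid[j[keep]]))
  }
  if (is.null(edges)) {
    comp <- seq_along(idx)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    if (igraph::vcount(g) < length(idx))
      g <- igraph::add_vertices(g, length(idx) - igraph::vcount(g))
    comp <- igraph::components(g)$membership
  }
  ## renumber components by first occurrence in column-major order
  first <- match(unique(comp), comp)
  ord <- order(idx[first])
  relab <- integer(max(comp))
  relab[comp[first][ord]] <- seq_along(ord)
  out[idx] <- relab[comp]
  out
}

#' Sub-pixel perimeter of a pixel set
#'
#' Length of the 0.5-level marching-squares contour around a binary pixel
#' set. The indicator is first smoothed with a Gaussian (sigma = 1 px) so
#' the contour tracks the underlying boundary at sub-pixel accuracy instead
#' of the pixelated staircase (which overestimates curved perimeters by
#' ~8%); if smoothing flattens the object below the 0.5 level (very small
#' objects), the raw indicator is contoured instead. Interior holes
#' contribute their boundary length.
#'
#' @param binary Logical (or 0/1) matrix, the pixel set.
#' @param smoothSigma Gaussian sigma for the indicator (px); default 1.
#' @return Perimeter length in pixels.
#' @export
contourPerimeter <- function(binary, smoothSigma = 1.0) {
  m <- matrix(as.numeric(binary > 0), nrow(binary), ncol(binary))
  pad <- max(4L, ceiling(4 * smoothSigma))
  big <- matrix(0, nrow(m) + 2 * pad, ncol(m) + 2 * pad)
  big[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  sm <- if (smoothSigma > 0) as.matrix(EBImage::gblur(big, smoothSigma)) else big
  if (max(sm) < 0.5) sm <- big
  cl <- grDevices::contourLines(x = seq_len(nrow(sm)), y = seq_len(ncol(sm)),
                                z = sm, levels = 0.5)
  if (!length(cl)) return(0)
  sum(vapply(cl, function(p) sum(sqrt(diff(p$x)^2 + diff(p$y)^2)), numeric(1)))
}

## condition helpers: stable message prefixes used as error identities
faStop <- function(code, fmt, ...) {
  stop(sprintf("%s: %s", code, sprintf(fmt, ...)), call. = FALSE)
}

## format a numeric at 6 significant digits for CSV output
signif6 <- function(x) {
  if (is.numeric(x)) signif(x, 6) else x
}
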