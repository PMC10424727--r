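# Poincare diagrams: successive-interval scatter (NN_i, NN_{i+1}) and its
# rasterization into classifier-ready intensity grids.

#' Build Poincare points from an NN series
#'
#' @param nn Numeric vector of NN intervals in seconds (length >= 2), or a
#'   \linkS4class{BeatSeries} whose \code{nn} slot is used.
#' @return A \linkS4class{PoincarePoints} with rows (NN_k, NN_{k+1}).
#' @export
buildPoints <- function(nn) {
  if (is(nn, "BeatSeries")) nn <- nn@nn
  if (length(nn) < 2)
    stop("need at least 2 NN intervals to form Poincare points")
  m <- cbind(nn[-length(nn)], nn[-1])
  colnames(m) <- c("nn_i", "nn_i1")
  new("PoincarePoints", points = m)
}

#' Rasterize Poincare points into a square intensity image
#'
#' Each point is rendered as a filled disc; intensities add per point (in
#' steps of \code{intensityStep}) and are clipped at 1 so that dense cloud
#' regions stay distinguishable. Points outside the axis range are clipped
#' to the border. Fixed default limits of 0.2--1.6 s keep absolute heart
#' rate visible to the classifier (a bradycardia cloud sits visibly higher
#' than a tachycardia cloud); pass \code{axisRange = NULL} for data-adaptive
#' limits.
#'
#' @param points A \linkS4class{PoincarePoints}.
#' @param size Image side in pixels (default 224).
#' @param axisRange Length-2 limits in seconds, or NULL for adaptive.
#' @param markerRadius Disc radius in pixels.
#' @param intensityStep Intensity added per point per covered pixel.
#' @return A \linkS4class{PoincareImage}. Row index follows NN_i, column
#'   index NN_{i+1}, so reversing the series transposes the image.
#' @export
rasterizePoints <- function(points, size = 224L, axisRange = c(0.2, 1.6),
                            markerRadius = 2L, intensityStep = 0.25) {
  pts <- points@points
  if (!nrow(pts)) stop("cannot rasterize an empty point set")
  if (is.null(axisRange)) {
    axisRange <- range(pts) + c(-0.05, 0.05)
  }
  if (axisRange[1] >= axisRange[2]) stop("axis_min must be < axis_max")
  size <- as.integer(size)
  toPx <- function(v) {
    p <- round((v - axisRange[1]) / (axisRange[2] - axisRange[1]) *
                 (size - 1)) + 1L
    pmin(pmax(p, 1L), size)  # clip out-of-range points to the border
  }
  ii <- toPx(pts[, 1])
  jj <- toPx(pts[, 2])
  r <- as.integer(markerRadius)
  off <- expand.grid(di = -r:r, dj = -r:r)
  off <- off[off$di^2 + off$dj^2 <= r^2, ]
  img <- matrix(0, size, size)
  for (k in seq_along(ii)) {
    pi_ <- ii[k] + off$di
    pj <- jj[k] + off$dj
    ok <- pi_ >= 1 & pi_ <= size & pj >= 1 & pj <= size
    idx <- cbind(pi_[ok], pj[ok])
    img[idx] <- img[idx] + intensityStep
  }
  img <- pmin(img, 1)
  new("PoincareImage", pixels = img, axisMin = axisRange[1],
      axisMax = axisRange[2], markerRadius = r)
}

#' Full record -> Poincare image pipeline
#'
#' Runs peak detection, NN filtering, point construction and rasterization.
#' Records with too few usable beats yield a blank image with a warning so
#' that batch processing never aborts.
#'
#' @param record An \linkS4class{EcgRecord}.
#' @param size,axisRange,markerRadius Passed to [rasterizePoints()].
#' @return A \linkS4class{PoincareImage}.
#' @export
recordToPoincare <- function(record, size = 224L, axisRange = c(0.2, 1.6),
                             markerRadius = 2L) {
  beats <- extractNN(detectRPeaks(record))
  if (length(beats@nn) < 2) {
    warning("record ", record@recordId,
            " has fewer than 2 NN intervals; blank Poincare image")
    return(new("PoincareImage", pixels = matrix(0, size, size),
               axisMin = axisRange[1], axisMax = axisRange[2],
               markerRadius = as.integer(markerRadius)))
  }
  rasterizePoints(buildPoints(beats), size = size, axisRange = axisRange,
                  markerRadius = markerRadius)
}

#' Short-term Poincare dispersion SD1
#'
#' SD1 is the dispersion of the point cloud perpendicular to the identity
#' line: \code{sd(diff(nn)) / sqrt(2)}. Used here as a summary statistic
#' (e.g. AF clouds disperse far more than sinus clouds at the same mean
#' rate), not as a classifier feature.
#'
#' @param nn NN interval vector or a \linkS4class{BeatSeries}.
#' @return SD1 in seconds.
#' @export
poincareSD1 <- function(nn) {
  if (is(nn, "BeatSeries")) nn <- nn@nn
  stats::sd(diff(nn)) / sqrt(2)
}

#' Export a Poincare image as a PNG file
#'
#' @param image A \linkS4class{PoincareImage}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writePoincarePng <- function(image, path) {
  # PNG rows run top to bottom; flip so the diagram origin is bottom-left
  m <- t(image@pixels)[rev(seq_len(ncol(image@pixels))), , drop = FALSE]
  png::writePNG(m, path)
  invisible(path)
}

# Image batch (H, W, 3, B) from a list of PoincareImages: the single
# intensity channel replicated to 3 channels for standard image backbones.
poincareBatch <- function(images) {
  size <- nrow(images[[1]]@pixels)
  B <- length(images)
  x <- array(0, c(size, size, 3, B))
  for (b in seq_len(B)) {
    x[, , 1, b] <- images[[b]]@pixels
    x[, , 2, b] <- images[[b]]@pixels
    x[, , 3, b] <- images[[b]]@pixels
  }
  x
}
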