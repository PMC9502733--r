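# Granularity: image-cytometry model of the FCM side-scatter (SSC)
# signal. SSC is proportional to internal complexity, so a summed
# gradient-type measurement over the nucleus interior is used. Five
# candidate operators are provided; the best one is chosen empirically
# by scoreOperators().

#' Supported granularity operators
#'
#' @return Character vector `c("dmg", "roberts", "prewitt", "sobel",
#'   "canny")`: discrete morphological gradient and the four classical
#'   edge detectors.
#' @export
granularityOperators <- function() c("dmg", "roberts", "prewitt", "sobel", "canny")

# Erosion radius used to suppress the object-boundary edge before
# summation, per operator footprint. Canny gets 2 (Gaussian smoothing
# plus the Sobel stencil widen its support).
granularityErosionRadius <- function(operator) {
  switch(operator,
         dmg = 1L, roberts = 1L, prewitt = 1L, sobel = 1L, canny = 2L,
         stop("unknown granularity operator: ", operator))
}

# Gradient-magnitude (or Canny binary edge) image over the whole raster.
granularityImage <- function(intensity, operator) {
  switch(operator,
    dmg = localExtreme(intensity, 1L, pmax) - localExtreme(intensity, 1L, pmin),
    roberts = {
      gx <- xcorr2(intensity, matrix(c(1, 0, 0, -1), 2, 2), anchor = c(1L, 1L))
      gy <- xcorr2(intensity, matrix(c(0, -1, 1, 0), 2, 2), anchor = c(1L, 1L))
      sqrt(gx^2 + gy^2)
    },
    prewitt = {
      kx <- matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3)
      gx <- xcorr2(intensity, kx)
      gy <- xcorr2(intensity, t(kx))
      sqrt(gx^2 + gy^2)
    },
    sobel = {
      kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
      gx <- xcorr2(intensity, kx)
      gy <- xcorr2(intensity, t(kx))
      sqrt(gx^2 + gy^2)
    },
    canny = cannyEdges(intensity),
    stop("unknown granularity operator: ", operator))
}

# Histogram-free Otsu threshold on a numeric vector (256 levels).
otsuThreshold <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) == 0 || diff(range(v)) == 0) return(Inf)
  breaks <- seq(min(v), max(v), length.out = 257)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  muT <- mu[256]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- 0
  k <- which.max(sigmaB)
  (breaks[k] + breaks[k + 1]) / 2
}

# Canny edge detection: Gaussian smoothing (sigma = 1), Sobel gradients,
# 4-direction non-maximum suppression, hysteresis with the high
# threshold from Otsu on the gradient magnitude and low = 0.4 * high.
# Returns a binary (0/1) edge map.
cannyEdges <- function(intensity, sigma = 1, lowFraction = 0.4) {
  r <- 3L
  g1 <- exp(-((-r:r)^2) / (2 * sigma^2)); g1 <- g1 / sum(g1)
  sm <- xcorr2(intensity, matrix(g1, nrow = 1), anchor = c(1L, r + 1L))
  sm <- xcorr2(sm, matrix(g1, ncol = 1), anchor = c(r + 1L, 1L))
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- xcorr2(sm, kx)
  gy <- xcorr2(sm, t(kx))
  mag <- sqrt(gx^2 + gy^2)

  # quantize gradient direction to 0/45/90/135 degrees
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  bin <- findInterval(ang, c(22.5, 67.5, 112.5, 157.5)) %% 4  # 0:E-W .. 3:NW-SE

  nr <- nrow(mag); nc <- ncol(mag)
  mp <- padReplicate(mag, 1L)
  sh <- function(a, b) mp[(1L + a) + seq_len(nr), (1L + b) + seq_len(nc)]
  # neighbour offsets along the gradient direction per direction bin;
  # rows grow downward so (dr, dc): bin0 grad ~ horizontal in gx sense
  n1 <- matrix(0, nr, nc); n2 <- matrix(0, nr, nc)
  offs <- list(`0` = list(c(0, 1), c(0, -1)),
               `1` = list(c(1, 1), c(-1, -1)),
               `2` = list(c(1, 0), c(-1, 0)),
               `3` = list(c(1, -1), c(-1, 1)))
  for (b in 0:3) {
    sel <- bin == b
    o <- offs[[as.character(b)]]
    n1[sel] <- sh(o[[1]][1], o[[1]][2])[sel]
    n2[sel] <- sh(o[[2]][1], o[[2]][2])[sel]
  }
  nms <- mag >= n1 & mag >= n2

  high <- otsuThreshold(mag[mag > 0])
  low <- lowFraction * high
  strong <- nms & mag >= high
  weak <- nms & mag >= low
  if (!any(weak)) return(matrix(0, nr, nc))
  comp <- EBImage::bwlabel(weak * 1)
  keep <- unique(comp[strong])
  keep <- keep[keep > 0]
  edges <- matrix(0, nr, nc)
  edges[comp %in% keep] <- 1
  edges
}

# Sum a precomputed operator map over the eroded object mask.
granularityFromMap <- function(image, objectId, map, erosionRadius) {
  mask <- image@labels == objectId
  inner <- erodeSquare(mask, erosionRadius)
  if (!any(inner)) {
    warning("object ", objectId, " has no interior after erosion; granularity 0")
    return(0)
  }
  sum(map[inner])
}

#' Nuclear granularity
#'
#' Sum of the operator's gradient magnitude (or Canny binary edge map)
#' over the object after eroding its mask by the operator's kernel
#' radius. The erosion suppresses the strong object/background boundary
#' edge so that the value reflects internal texture rather than
#' perimeter. The sum (not mean) mirrors the integral nature of the FCM
#' SSC signal.
#'
#' @inheritParams backgroundAnnulus
#' @param operator one of [granularityOperators()].
#' @return Single numeric granularity value (0, with a warning, when the
#'   object has no interior after erosion).
#' @export
granularity <- function(image, objectId, operator = "dmg") {
  stopifnot(is(image, "LabeledImage"))
  operator <- match.arg(operator, granularityOperators())
  if (!any(image@labels == objectId))
    stop("object ", objectId, " not present in label mask")
  map <- granularityImage(image@intensity, operator)
  granularityFromMap(image, objectId, map,
                     erosionRadius = granularityErosionRadius(operator))
}
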