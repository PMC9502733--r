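# Per-sample PCA over (area, DNA content, granularity): verifies the
# near-independence of the three measurements and yields noise-filtered
# coordinates for population identification.

#' Fit a per-sample PCA of the three nucleus measurements
#'
#' Eigen-decomposition of the covariance of the centered (and optionally
#' per-feature scaled) matrix of area, DNA content and granularity. Sign
#' convention: each component's largest-magnitude loading is positive.
#' Components are identified by their dominant loading, giving a
#' component-to-feature mapping that is bijective when the three
#' measurements are nearly independent.
#'
#' The default `scaling = "none"` performs covariance PCA on the raw
#' measurement scales, whose order-of-magnitude separation (integrated
#' density >> granularity >> area) pins each component to one feature
#' when cross-correlations are small, producing the near-axis loading
#' structure expected of independent measurements. Unit-variance scaling
#' is available but destroys that separation: the correlation matrix of
#' a weakly coupled pair has eigenvectors at 45 degrees however small
#' the coupling.
#'
#' @param features data.frame with numeric columns `area`, `dna`,
#'   `gran` (at least 3 rows, finite values).
#' @param scaling `"none"` (covariance PCA) or `"unit_variance"`.
#' @return A [PloidyPca-class].
#' @export
fitPloidyPca <- function(features, scaling = c("none", "unit_variance")) {
  scaling <- match.arg(scaling)
  cols <- c("area", "dna", "gran")
  stopifnot(all(cols %in% names(features)))
  X <- as.matrix(features[, cols])
  stopifnot(nrow(X) >= 3, all(is.finite(X)))

  center <- colMeans(X)
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    warning("zero-variance feature; rank-deficient input")
  sf <- if (scaling == "unit_variance") sds else rep(1, 3)
  sf[sf == 0] <- 1
  names(sf) <- cols
  Xs <- sweep(sweep(X, 2, center), 2, sf, "/")

  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  rot <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  mapping <- cols[apply(abs(rot), 2, which.max)]
  names(mapping) <- colnames(rot)
  if (length(unique(mapping)) < length(mapping))
    warning("component-to-feature mapping is not bijective; ",
            "dominant loadings are ambiguous")

  new("PloidyPca", coefficients = rot,
      explainedVariance = as.numeric(pc$sdev^2),
      mapping = mapping, scores = scores, center = center,
      scaleFactors = sf, scaling = scaling)
}

#' PCA noise filtering of the nucleus measurements
#'
#' Replaces each measurement by the coordinate of the principal
#' component it dominates, rescaled back to original units (score times
#' the feature's scale factor, plus its mean). With nearly independent
#' inputs this is a small rotation that strips the minor-component noise
#' from each measurement; correcting already-corrected data is a no-op
#' up to numerical tolerance.
#'
#' @param features data.frame with columns `area`, `dna`, `gran` (the
#'   data the PCA was fitted on).
#' @param pca a [PloidyPca-class] with a bijective component mapping.
#' @return data.frame with columns `area_denoised`, `dna_denoised`,
#'   `gran_denoised`.
#' @export
pcaCorrect <- function(features, pca) {
  stopifnot(is(pca, "PloidyPca"))
  mapping <- pca@mapping
  if (length(unique(mapping)) < 3)
    stop("component-to-feature mapping is not bijective; ",
         "inspect pcaLoadings() before correcting")
  cols <- c("area", "dna", "gran")
  X <- as.matrix(features[, cols])
  Xs <- sweep(sweep(X, 2, pca@center), 2, pca@scaleFactors, "/")
  scores <- Xs %*% pca@coefficients
  out <- lapply(cols, function(f) {
    comp <- which(mapping == f)
    scores[, comp] * pca@scaleFactors[f] + pca@center[f]
  })
  names(out) <- paste0(cols, "_denoised")
  as.data.frame(out)
}
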