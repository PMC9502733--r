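#' @import methods
#' @importFrom stats coef kmeans lm median prcomp quantile residuals rnorm
#'   runif sd set.seed shapiro.test
#' @importFrom utils read.csv write.csv
NULL

#' Labeled intensity image
#'
#' Container pairing a grayscale fluorescence intensity raster with an
#' integer-labeled segmentation mask of identical dimensions. Label 0 is
#' background; every positive label k denotes the pixels of object k
#' (a cell nucleus).
#'
#' @slot intensity numeric matrix of non-negative pixel intensities.
#' @slot labels integer matrix of object labels (0 = background).
#'
#' @seealso [LabeledImage()] for construction, [extractFeatures()] for
#'   per-nucleus measurement.
#' @export
setClass("LabeledImage",
  representation(intensity = "matrix", labels = "matrix"),
  validity = function(object) {
    msg <- character(0)
    if (!all(dim(object@intensity) == dim(object@labels)))
      msg <- c(msg, "intensity and labels must have identical dimensions")
    if (any(object@labels < 0))
      msg <- c(msg, "labels must be non-negative integers")
    if (any(object@labels != floor(object@labels)))
      msg <- c(msg, "labels must be whole numbers")
    if (any(!is.finite(object@intensity)))
      msg <- c(msg, "intensity must be finite")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a LabeledImage
#'
#' @param intensity numeric matrix of pixel intensities.
#' @param labels matrix of integer object labels, same dimensions; 0 is
#'   background.
#' @return A [LabeledImage-class] object.
#' @examples
#' im <- LabeledImage(matrix(10, 8, 8), matrix(0L, 8, 8))
#' im
#' @export
LabeledImage <- function(intensity, labels) {
  new("LabeledImage",
      intensity = as.matrix(intensity),
      labels = matrix(as.integer(round(labels)), nrow(labels), ncol(labels)))
}

setMethod("show", "LabeledImage", function(object) {
  ids <- objectIds(object)
  cat("LabeledImage: ", nrow(object@intensity), " x ", ncol(object@intensity),
      " pixels, ", length(ids), " labeled object",
      if (length(ids) != 1) "s", "\n", sep = "")
  cat("  intensity range: [", min(object@intensity), ", ",
      max(object@intensity), "]\n", sep = "")
})

#' Background-annulus configuration
#'
#' Parameters of the local background neighborhood used for integrated
#' density: pixels at Euclidean distance in (d, D] from the measured
#' object, excluding pixels within d of any object, form the background
#' set. Defaults follow the study design: D = 35 px (the average object
#' size at the working magnification) and d = 5 px (the distance beyond
#' which object proximity no longer biases intensities).
#'
#' @param D outer neighborhood radius in pixels.
#' @param d exclusion distance in pixels; must satisfy `D > d > 0`.
#' @return A list with elements `D` and `d`.
#' @export
backgroundConfig <- function(D = 35, d = 5) {
  stopifnot(is.numeric(D), is.numeric(d), length(D) == 1, length(d) == 1)
  if (!(D > d && d > 0)) stop("backgroundConfig requires D > d > 0")
  list(D = D, d = d)
}

#' Gap-statistic result
#'
#' @slot kValues integer vector of evaluated cluster counts.
#' @slot gap numeric gap value per k.
#' @slot sk numeric reference-dispersion standard error per k.
#' @slot logW numeric log within-cluster dispersion of the data per k.
#' @slot bestK integer, the selected cluster count.
#' @export
setClass("GapResult",
  representation(kValues = "integer", gap = "numeric", sk = "numeric",
                 logW = "numeric", bestK = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@gap) != length(object@kValues))
      msg <- c(msg, "gap and kValues lengths differ")
    if (length(object@sk) != length(object@kValues))
      msg <- c(msg, "sk and kValues lengths differ")
    if (!(object@bestK %in% object@kValues))
      msg <- c(msg, "bestK must be one of kValues")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "GapResult", function(object) {
  cat("GapResult over k =", paste(range(object@kValues), collapse = ".."),
      "- selected k =", object@bestK, "\n")
  print(data.frame(k = object@kValues, gap = round(object@gap, 4),
                   sk = round(object@sk, 4)), row.names = FALSE)
})

#' Per-sample PCA of (area, DNA content, granularity)
#'
#' @slot coefficients 3x3 loading matrix; columns are components, rows the
#'   measured features.
#' @slot explainedVariance variance explained per component.
#' @slot mapping named character: for each component, the feature carrying
#'   its largest absolute loading.
#' @slot scores per-object component coordinates.
#' @slot center feature means removed before decomposition.
#' @slot scaleFactors per-feature divisors (1 when `scaling = "none"`).
#' @slot scaling scaling mode used.
#' @export
setClass("PloidyPca",
  representation(coefficients = "matrix", explainedVariance = "numeric",
                 mapping = "character", scores = "matrix",
                 center = "numeric", scaleFactors = "numeric",
                 scaling = "character"))

setMethod("show", "PloidyPca", function(object) {
  cat("PloidyPca (scaling =", object@scaling, ")\n")
  cat("  explained variance:",
      paste(signif(object@explainedVariance, 4), collapse = ", "), "\n")
  cat("  component mapping:",
      paste(names(object@mapping), object@mapping, sep = "->",
            collapse = ", "), "\n")
})

#' Fuzzy c-means clustering result
#'
#' @slot centers c x p matrix of cluster centers.
#' @slot memberships n x c membership matrix U; rows sum to 1.
#' @slot m fuzzifier exponent.
#' @slot iterations iterations run.
#' @slot converged whether the center-shift tolerance was reached.
#' @export
setClass("FuzzyClustering",
  representation(centers = "matrix", memberships = "matrix", m = "numeric",
                 iterations = "integer", converged = "logical"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@centers) != ncol(object@memberships))
      msg <- c(msg, "centers rows must equal membership columns")
    if (any(object@memberships < -1e-12 | object@memberships > 1 + 1e-12))
      msg <- c(msg, "memberships must lie in [0, 1]")
    if (any(abs(rowSums(object@memberships) - 1) > 1e-9))
      msg <- c(msg, "membership rows must sum to 1")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "FuzzyClustering", function(object) {
  cat("FuzzyClustering:", ncol(object@memberships), "clusters,",
      nrow(object@memberships), "points, m =", object@m, "\n")
  cat("  iterations:", object@iterations,
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  cat("  centers:\n")
  print(round(object@centers, 4))
})

#' Cohort-level ICM-to-FCM calibration
#'
#' Holds the cross-sample transfer function between image-cytometry DNA
#' content and flow-cytometry channel units: per-sample scales, their
#' naive mean, pooled linear regressions with and without intensity
#' outliers, peak-ratio statistics per method, and outlier flags.
#'
#' @slot scales per-sample least-squares scale through the origin.
#' @slot naiveScale arithmetic mean of the per-sample scales.
#' @slot naiveSD sample standard deviation of the per-sample scales.
#' @slot regression list of pooled-regression fits per ICM method (all
#'   samples).
#' @slot regressionExcluded same, after intensity-outlier exclusion.
#' @slot ratioStats data.frame of peak-ratio mean/SD per method.
#' @slot outlierFlags logical per sample.
#' @export
setClass("CohortCalibration",
  representation(scales = "numeric", naiveScale = "numeric",
                 naiveSD = "numeric", regression = "list",
                 regressionExcluded = "list", ratioStats = "data.frame",
                 outlierFlags = "logical"),
  validity = function(object) {
    msg <- character(0)
    for (r in c(object@regression, object@regressionExcluded)) {
      if (!is.null(r$rmse) && r$rmse < 0) msg <- c(msg, "RMSE must be >= 0")
      if (!is.null(r$r_squared) && r$r_squared > 1 + 1e-12)
        msg <- c(msg, "R-squared must be <= 1")
    }
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "CohortCalibration", function(object) {
  cat("CohortCalibration over", length(object@scales), "samples\n")
  cat("  naive scale:", signif(object@naiveScale, 6),
      "(SD", signif(object@naiveSD, 6), ")\n")
  cat("  intensity outliers:", sum(object@outlierFlags), "flagged\n")
  cat("  peak-ratio statistics:\n")
  print(object@ratioStats, row.names = FALSE)
  for (nm in names(object@regression)) {
    r <- object@regression[[nm]]
    cat(sprintf("  regression [%s]: slope %.6g intercept %.6g RMSE %.4g R2 %.4g\n",
                nm, r$slope, r$intercept, r$rmse, r$r_squared))
  }
})
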