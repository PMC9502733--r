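#' @rdname LabeledImage-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))
#' @rdname LabeledImage-class
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))
#' @rdname LabeledImage-class
#' @export
setGeneric("objectIds", function(x) standardGeneric("objectIds"))

#' @rdname GapResult-class
#' @param x an object of the documented class.
#' @export
setGeneric("bestK", function(x) standardGeneric("bestK"))
#' @rdname GapResult-class
#' @export
setGeneric("gapValues", function(x) standardGeneric("gapValues"))

#' @rdname FuzzyClustering-class
#' @param x an object of the documented class.
#' @export
setGeneric("memberships", function(x) standardGeneric("memberships"))
#' @rdname FuzzyClustering-class
#' @export
setGeneric("clusterCenters", function(x) standardGeneric("clusterCenters"))

#' @rdname PloidyPca-class
#' @param x an object of the documented class.
#' @export
setGeneric("pcaLoadings", function(x) standardGeneric("pcaLoadings"))
#' @rdname PloidyPca-class
#' @export
setGeneric("pcaScores", function(x) standardGeneric("pcaScores"))
#' @rdname PloidyPca-class
#' @export
setGeneric("componentMapping", function(x) standardGeneric("componentMapping"))

#' @rdname CohortCalibration-class
#' @param x an object of the documented class.
#' @export
setGeneric("naiveScale", function(x) standardGeneric("naiveScale"))
#' @rdname CohortCalibration-class
#' @export
setGeneric("sampleScales", function(x) standardGeneric("sampleScales"))
#' @rdname CohortCalibration-class
#' @export
setGeneric("outlierFlags", function(x) standardGeneric("outlierFlags"))
#' @rdname CohortCalibration-class
#' @export
setGeneric("regressionTable", function(x, ...) standardGeneric("regressionTable"))
#' @rdname CohortCalibration-class
#' @export
setGeneric("ratioStatsTable", function(x) standardGeneric("ratioStatsTable"))

#' @rdname LabeledImage-class
#' @export
setMethod("intensityMatrix", "LabeledImage", function(x) x@intensity)
#' @rdname LabeledImage-class
#' @export
setMethod("labelMatrix", "LabeledImage", function(x) x@labels)
#' @rdname LabeledImage-class
#' @export
setMethod("objectIds", "LabeledImage", function(x) {
  ids <- sort(unique(as.vector(x@labels)))
  ids[ids > 0]
})

#' @rdname GapResult-class
#' @export
setMethod("bestK", "GapResult", function(x) x@bestK)
#' @rdname GapResult-class
#' @export
setMethod("gapValues", "GapResult", function(x)
  data.frame(k = x@kValues, gap = x@gap, sk = x@sk, logW = x@logW))

#' @rdname FuzzyClustering-class
#' @export
setMethod("memberships", "FuzzyClustering", function(x) x@memberships)
#' @rdname FuzzyClustering-class
#' @export
setMethod("clusterCenters", "FuzzyClustering", function(x) x@centers)

#' @rdname PloidyPca-class
#' @export
setMethod("pcaLoadings", "PloidyPca", function(x) x@coefficients)
#' @rdname PloidyPca-class
#' @export
setMethod("pcaScores", "PloidyPca", function(x) x@scores)
#' @rdname PloidyPca-class
#' @export
setMethod("componentMapping", "PloidyPca", function(x) x@mapping)

#' @rdname CohortCalibration-class
#' @export
setMethod("naiveScale", "CohortCalibration", function(x)
  c(scale = x@naiveScale, sd = x@naiveSD))
#' @rdname CohortCalibration-class
#' @export
setMethod("sampleScales", "CohortCalibration", function(x) x@scales)
#' @rdname CohortCalibration-class
#' @export
setMethod("outlierFlags", "CohortCalibration", function(x) x@outlierFlags)
#' @rdname CohortCalibration-class
#' @param excluded logical; return the fits after outlier exclusion.
#' @param ... passed between methods.
#' @export
setMethod("regressionTable", "CohortCalibration", function(x, excluded = FALSE) {
  fits <- if (excluded) x@regressionExcluded else x@regression
  do.call(rbind, lapply(names(fits), function(nm) {
    r <- fits[[nm]]
    data.frame(method = nm, slope = r$slope, intercept = r$intercept,
               rmse = r$rmse, r_squared = r$r_squared,
               shapiro_w = r$shapiro_w, shapiro_p = r$shapiro_p, n = r$n)
  }))
})
#' @rdname CohortCalibration-class
#' @export
setMethod("ratioStatsTable", "CohortCalibration", function(x) x@ratioStats)
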