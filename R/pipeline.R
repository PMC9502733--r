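# End-to-end orchestration: per-sample population identification and
# peak estimation on both modalities, then cohort calibration.

#' Default pipeline parameters
#'
#' @return Nested list of defaults for every stage: background annulus
#'   radii, histogram bin count, fuzzy c-means settings, gap-statistic
#'   settings, PCA scaling, and calibration options.
#' @export
pipelineDefaults <- function() {
  list(
    background = list(D = 35, d = 5),
    histogram = list(bin_count = 256),
    pca = list(scaling = "none"),
    cmeans = list(c = 3, m = 2, threshold = 0.6, tol = 1e-5,
                  max_iter = 300, seed = 1),
    gap = list(k_max = 6, B = 50, seed = 1),
    calibration = list(pooling = "both_peaks", manual_exclude = integer(0)),
    seed = 1
  )
}

# Cluster 1-D or 2-D DNA-bearing coordinates into debris/2N/4N and
# estimate both peaks for the 2N and 4N populations. Clustering runs on
# the raw (denoised) coordinates, so the DNA axis -- the discriminative
# one, orders of magnitude wider than area -- dominates the metric as it
# does in the study's component-plane scatterplots.
#   coords: matrix whose last column is the DNA coordinate
# Returns peak rows plus the assignment, or signals an error when the
# sample is mis-clustered / a population is too small.
clusterAndPeaks <- function(coords, params, seed) {
  coords <- as.matrix(coords)
  dnaCol <- ncol(coords)
  fc <- fuzzyCMeans(coords, c = params$cmeans$c, m = params$cmeans$m,
                    tol = params$cmeans$tol, maxIter = params$cmeans$max_iter,
                    seed = seed)
  dnaCenters <- clusterCenters(fc)[, dnaCol]
  assign <- labelPopulations(fc, dnaCenters)
  if (attr(assign, "flagged"))
    stop("sample flagged: 4N/2N center ratio ",
         signif(attr(assign, "ratio"), 4), " outside [1.5, 2.5]")
  kept <- filterUncertain(fc, params$cmeans$threshold)
  assign$population[!kept] <- "unassigned"

  dna <- coords[, dnaCol]
  rngAll <- range(dna)
  peaks <- do.call(rbind, lapply(c("2N", "4N"), function(pop) {
    vals <- dna[kept & assign$population == pop]
    bp <- histogramPeak(vals, binCount = params$histogram$bin_count,
                        range = rngAll)
    gf <- fitNormalPeak(vals, binCount = params$histogram$bin_count,
                        range = rngAll)
    bp$population <- gf$population <- pop
    bp[setdiff(names(gf), names(bp))] <- NA
    rbind(bp, gf[names(bp)])
  }))
  list(peaks = peaks, assignment = assign)
}

#' Analyze one paired sample
#'
#' Runs the per-sample analysis chain on an event sample: PCA denoising
#' of the ICM (area, DNA, granularity) features, fuzzy c-means
#' population identification with uncertainty filtering on the denoised
#' (area, DNA) plane, peak estimation (modal bin and Gaussian fit) for
#' the 2N and 4N populations, and the same clustering/peak chain on the
#' 1-D FCM event values.
#'
#' @param sample list as returned by [generateEventSample()] (elements
#'   `features` with `area`, `dna`, granularity columns, and `events`
#'   with `fsc_area`), or equivalent measured data.
#' @param params nested parameter list, see [pipelineDefaults()].
#' @param granColumn granularity column used for the PCA
#'   (default `gran_dmg`, the selected operator of the study design).
#' @param seed seed for the clustering stages.
#' @return List: `peaks` (data.frame with `modality`, `population`,
#'   `method`, `location`, ...), `ratios` (per method), `icmAssignment`,
#'   `pca`.
#' @export
analyzeSample <- function(sample, params = pipelineDefaults(),
                          granColumn = "gran_dmg", seed = params$seed) {
  ft <- sample$features
  stopifnot(all(c("area", "dna", granColumn) %in% names(ft)))
  seeds <- deriveSeeds(seed, 2)

  pcaIn <- data.frame(area = ft$area, dna = ft$dna, gran = ft[[granColumn]])
  pca <- fitPloidyPca(pcaIn, scaling = params$pca$scaling)
  den <- pcaCorrect(pcaIn, pca)

  icm <- clusterAndPeaks(cbind(den$area_denoised, den$dna_denoised),
                         params, seeds[1])
  icm$peaks$modality <- "icm"
  fcm <- clusterAndPeaks(matrix(sample$events$fsc_area, ncol = 1),
                         params, seeds[2])
  fcm$peaks$modality <- "fcm"
  peaks <- rbind(icm$peaks, fcm$peaks)

  getLoc <- function(modality, method, pop)
    peaks$location[peaks$modality == modality & peaks$method == method &
                   peaks$population == pop]
  ratios <- data.frame(
    method = c("fcm_bin", "icm_bin", "icm_fit"),
    ratio = c(getLoc("fcm", "bin_peak", "4N") / getLoc("fcm", "bin_peak", "2N"),
              getLoc("icm", "bin_peak", "4N") / getLoc("icm", "bin_peak", "2N"),
              getLoc("icm", "gauss_fit", "4N") / getLoc("icm", "gauss_fit", "2N")))

  list(peaks = peaks, ratios = ratios, icmAssignment = icm$assignment,
       pca = pca)
}

#' Run the full cohort pipeline
#'
#' Analyzes every sample of a cohort ([analyzeSample()]), quarantining
#' samples that fail (mis-clustered or under-populated) and continuing;
#' the run aborts only when fewer than 3 samples survive. The surviving
#' peak tables are then calibrated cohort-wide ([calibrateCohort()]):
#' peak-ratio statistics for the three method variants (FCM bin peaks,
#' ICM bin peaks, ICM fitted peaks), per-sample scales and their naive
#' mean, and pooled ICM-to-FCM regressions with and without
#' intensity-outlier exclusion.
#'
#' A fixed `params$seed` makes the whole run deterministic.
#'
#' @param cohort a `ploidyCohort` from [generateCohort()], or a list
#'   with element `samples` (each as in [analyzeSample()]).
#' @param params nested parameter list, see [pipelineDefaults()].
#' @param granColumn granularity column used for PCA denoising.
#' @return List of class `ploidyRunReport`: `ratio_stats`,
#'   `naive_scale`, `regression`, `regression_excluded`,
#'   `outlier_flags`, `sample_ratios`, `peak_table`, `quarantined`,
#'   `params`, and the `calibration` object.
#' @export
runPipeline <- function(cohort, params = pipelineDefaults(),
                        granColumn = "gran_dmg") {
  samples <- if (inherits(cohort, "ploidyCohort")) cohort$samples
             else cohort$samples
  nS <- length(samples)
  seeds <- deriveSeeds(params$seed, nS)
  results <- vector("list", nS)
  quarantined <- character(0)
  for (i in seq_len(nS)) {
    res <- tryCatch(
      analyzeSample(samples[[i]], params, granColumn, seed = seeds[i]),
      error = function(e) {
        warning("sample ", i, " quarantined: ", conditionMessage(e))
        NULL
      })
    results[i] <- list(res)
    if (is.null(res))
      quarantined <- c(quarantined, as.character(i))
  }
  ok <- which(!vapply(results, is.null, TRUE))
  if (length(ok) < 3)
    stop("fewer than 3 samples survived analysis (",
         length(ok), " of ", nS, ")")

  peakTable <- do.call(rbind, lapply(ok, function(i) {
    p <- results[[i]]$peaks
    p$sample_id <- i
    p
  }))
  ratioTable <- do.call(rbind, lapply(ok, function(i) {
    r <- results[[i]]$ratios
    r$sample_id <- i
    r
  }))

  getLoc <- function(i, modality, method, pop) {
    p <- results[[i]]$peaks
    p$location[p$modality == modality & p$method == method &
               p$population == pop]
  }
  pairs <- do.call(rbind, lapply(ok, function(i) {
    do.call(rbind, lapply(c(icm_bin = "bin_peak", icm_fit = "gauss_fit"),
                          function(mth) {
      data.frame(sample_id = i, method = NA_character_,
                 icm_2N = getLoc(i, "icm", mth, "2N"),
                 icm_4N = getLoc(i, "icm", mth, "4N"),
                 fcm_2N = getLoc(i, "fcm", "bin_peak", "2N"),
                 fcm_4N = getLoc(i, "fcm", "bin_peak", "4N"))
    }))
  }))
  pairs$method <- rep(c("icm_bin", "icm_fit"), length(ok))

  allRatios <- rbind(
    data.frame(method = ratioTable$method, ratio = ratioTable$ratio))
  calib <- calibrateCohort(pairs, ratioTable = allRatios,
                           scaleMethod = "icm_fit",
                           manualExclude = params$calibration$manual_exclude,
                           pooling = params$calibration$pooling)

  report <- list(
    n_samples = nS,
    n_analyzed = length(ok),
    quarantined = quarantined,
    ratio_stats = ratioStatsTable(calib),
    naive_scale = as.list(naiveScale(calib)),
    regression = regressionTable(calib, excluded = FALSE),
    regression_excluded = regressionTable(calib, excluded = TRUE),
    outlier_flags = which(outlierFlags(calib)),
    sample_ratios = ratioTable,
    peak_table = peakTable,
    params = params,
    calibration = calib)
  class(report) <- "ploidyRunReport"
  report
}

#' @export
print.ploidyRunReport <- function(x, ...) {
  cat("ploidyRunReport:", x$n_analyzed, "of", x$n_samples,
      "samples analyzed\n")
  cat("peak-ratio statistics (theoretical ratio: 2.0):\n")
  print(x$ratio_stats, row.names = FALSE)
  cat("naive ICM->FCM scale:", signif(x$naive_scale$scale, 6),
      "(SD", signif(x$naive_scale$sd, 6), ")\n")
  cat("regression (all samples):\n")
  print(x$regression[, c("method", "slope", "intercept", "rmse",
                         "r_squared", "shapiro_p")], row.names = FALSE)
  if (length(x$outlier_flags))
    cat("low-intensity outlier samples:",
        paste(x$outlier_flags, collapse = ", "), "\n")
  invisible(x)
}
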