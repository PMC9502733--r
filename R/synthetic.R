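# Synthetic paired FCM/ICM data with known ground truth. A healthy-blood
# sample is modeled as two nucleus populations whose mean DNA contents
# are in exact 1:2 relation (2N and 4N) plus a low-intensity debris
# fraction; the same underlying cells are rendered both as flow-cytometry
# events (FSC-area channel) and as image-cytometry feature rows or
# rendered image scenes.

#' Specification of one synthetic sample
#'
#' @param nCells number of cells (>= 50 for event samples).
#' @param mu2N mean ICM DNA-content intensity of the 2N population,
#'   arbitrary integrated-density units.
#' @param cv within-population coefficient of variation (fraction);
#'   applied as independent multiplicative Gaussian noise in each
#'   modality.
#' @param frac4N fraction of cells in the 4N population.
#' @param fracDebris fraction of low-intensity debris objects.
#' @param fcmScale multiplicative factor mapping true DNA content to FCM
#'   channel units.
#' @param icmScale per-sample global ICM intensity multiplier (models
#'   exposure/bleaching differences between slides).
#' @param seed random seed.
#' @return Validated list of the above fields.
#' @export
sampleSpec <- function(nCells = 2000, mu2N = 50000, cv = 0.04,
                       frac4N = 0.25, fracDebris = 0.1,
                       fcmScale = 0.01, icmScale = 1, seed = 1) {
  stopifnot(mu2N > 0, cv >= 0, frac4N >= 0, fracDebris >= 0,
            fcmScale > 0, icmScale > 0)
  if (frac4N + fracDebris >= 1)
    stop("frac4N + fracDebris must be < 1")
  list(nCells = as.integer(nCells), mu2N = mu2N, cv = cv, frac4N = frac4N,
       fracDebris = fracDebris, fcmScale = fcmScale, icmScale = icmScale,
       seed = as.integer(seed))
}

#' Specification of a rendered image scene
#'
#' @param imageSize c(height, width) in pixels.
#' @param radiusRange nucleus radius bounds in pixels.
#' @param textureAmplitude relative amplitude of the sinusoidal internal
#'   intensity modulation of 2N nuclei (4N nuclei get 1.5 times this,
#'   making granularity weakly informative about ploidy).
#' @param backgroundLevel base background intensity.
#' @param backgroundGradient total linear intensity ramp across the frame
#'   width (0 for flat background).
#' @param noiseSd additive Gaussian pixel noise SD.
#' @param minSeparation minimum center-to-center distance between
#'   nuclei, pixels.
#' @param seed random seed for placement/rendering.
#' @return Validated list of the above fields.
#' @export
imageSceneSpec <- function(imageSize = c(512, 512), radiusRange = c(14, 20),
                           textureAmplitude = 0.3, backgroundLevel = 500,
                           backgroundGradient = 0, noiseSd = 2,
                           minSeparation = 48, seed = 1) {
  stopifnot(length(imageSize) == 2, all(imageSize > 0),
            length(radiusRange) == 2, radiusRange[1] <= radiusRange[2],
            radiusRange[1] > 0, textureAmplitude >= 0,
            backgroundLevel >= 0, noiseSd >= 0, minSeparation > 0)
  list(imageSize = as.integer(imageSize), radiusRange = radiusRange,
       textureAmplitude = textureAmplitude, backgroundLevel = backgroundLevel,
       backgroundGradient = backgroundGradient, noiseSd = noiseSd,
       minSeparation = minSeparation, seed = as.integer(seed))
}

# Draw population labels and exact (noise-free) DNA contents. The 4N
# mean is exactly twice the 2N mean; debris is uniform on (0, 0.7*mu2N).
drawTrueContents <- function(spec) {
  n <- spec$nCells
  pop <- sample(c("debris", "2N", "4N"), n, replace = TRUE,
                prob = c(spec$fracDebris,
                         1 - spec$fracDebris - spec$frac4N, spec$frac4N))
  content <- numeric(n)
  content[pop == "2N"] <- spec$mu2N
  content[pop == "4N"] <- 2 * spec$mu2N
  nd <- sum(pop == "debris")
  content[pop == "debris"] <- runif(nd, 0, 0.7 * spec$mu2N)
  list(pop = pop, content = content)
}

# Multiplicative Gaussian noise with CV cv (scalar or per-element),
# truncated at 0 by redraw.
cvNoise <- function(x, cv) {
  if (all(cv == 0)) return(x)
  cv <- rep_len(cv, length(x))
  out <- x * (1 + cv * rnorm(length(x)))
  bad <- which(out <= 0 & x > 0)
  while (length(bad)) {
    out[bad] <- x[bad] * (1 + cv[bad] * rnorm(length(bad)))
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Generate one paired FCM/ICM event sample
#'
#' Draws one synthetic sample: every cell gets a true DNA content (2N
#' mean `mu2N`, 4N mean exactly `2 * mu2N`, debris uniform below
#' `0.7 * mu2N`), then the same cells are observed through both
#' instruments with independent multiplicative noise:
#' `FCM = fcmScale * content * (1 + cv * z)` and
#' `ICM = icmScale * content * (1 + cv * z')`. Pixel area and one
#' granularity column per operator are drawn with population-dependent
#' means (4N granularity 1.5x that of 2N; the Sobel and Canny columns are
#' deliberately noisy/uninformative to exercise operator selection).
#'
#' @param spec a [sampleSpec()].
#' @return List with elements `events` (data.frame `event_id`,
#'   `fsc_area`), `features` (data.frame `object_id`, `area`, `dna`,
#'   `gran_dmg` ... `gran_canny`), `truth` (data.frame `object_id`,
#'   `population`, `true_content`, `true_area`), and `spec`.
#' @export
generateEventSample <- function(spec) {
  if (spec$nCells < 50)
    stop("nCells must be >= 50 for downstream histogramming")
  withSeed(spec$seed, {
    tc <- drawTrueContents(spec)
    n <- spec$nCells
    fcm <- cvNoise(spec$fcmScale * tc$content, spec$cv)
    icm <- cvNoise(spec$icmScale * tc$content, spec$cv)

    areaBase <- ifelse(tc$pop == "debris", 120,
                       ifelse(tc$pop == "2N", 350, 350 * 1.06))
    area <- cvNoise(areaBase, ifelse(tc$pop == "debris", 0.15, 0.08))
    granBase <- ifelse(tc$pop == "debris", 300,
                       ifelse(tc$pop == "2N", 1000, 1500)) * spec$icmScale
    # granularity is a noisy texture readout in practice; operator columns
    # differ in how faithfully they track the underlying signal (the sobel
    # column is heavily degraded, the canny column carries no signal)
    features <- data.frame(
      object_id = seq_len(n),
      area = area,
      dna = icm,
      gran_dmg = cvNoise(granBase, max(0.12, spec$cv)),
      gran_roberts = cvNoise(granBase, max(0.2, spec$cv)),
      gran_prewitt = cvNoise(granBase, max(0.13, spec$cv)),
      gran_sobel = cvNoise(granBase, 0.8),
      gran_canny = runif(n, 0, 2000 * spec$icmScale))
    list(events = data.frame(event_id = seq_len(n), fsc_area = fcm),
         features = features,
         truth = data.frame(object_id = seq_len(n), population = tc$pop,
                            true_content = tc$content, true_area = area),
         spec = spec)
  })
}

#' Render a labeled image scene for one sample
#'
#' Places `spec$nCells` disk-shaped nuclei with sinusoidal internal
#' texture on a background with optional linear gradient and additive
#' Gaussian noise, quantized to a 16-bit integer raster. The recorded
#' ground-truth integrated density of each object is the exact sum of
#' its painted above-background increments after quantization (so a
#' noise-free scene reproduces it exactly through [extractFeatures()]).
#'
#' @param spec a [sampleSpec()]; `nCells` nuclei are rendered.
#' @param scene an [imageSceneSpec()].
#' @return List with `image` (a [LabeledImage-class]) and `truth`
#'   (data.frame `object_id`, `population`, `true_iod`, `true_area`).
#' @export
generateImageSample <- function(spec, scene = imageSceneSpec()) {
  withSeed(scene$seed, {
    h <- scene$imageSize[1]; w <- scene$imageSize[2]
    n <- spec$nCells
    rmax <- scene$radiusRange[2]
    if (h < 2 * (rmax + 2) || w < 2 * (rmax + 2))
      stop("scene too small to host any object of radius ", rmax)

    tc <- drawTrueContents(spec)
    radii <- runif(n, scene$radiusRange[1], scene$radiusRange[2])

    # rejection-sample centers at min separation, bounded retries
    centers <- matrix(NA_real_, n, 2)
    tries <- 0L; maxTries <- 1000L * n
    placed <- 0L
    while (placed < n) {
      if (tries >= maxTries)
        stop("could not place ", n, " objects of radius <= ", rmax,
             " at minSeparation = ", scene$minSeparation,
             " in a ", h, "x", w, " frame")
      tries <- tries + 1L
      r <- radii[placed + 1L]
      cy <- runif(1, r + 2, h - r - 1)
      cx <- runif(1, r + 2, w - r - 1)
      if (placed == 0L ||
          min((centers[seq_len(placed), 1] - cy)^2 +
              (centers[seq_len(placed), 2] - cx)^2) >=
            scene$minSeparation^2) {
        placed <- placed + 1L
        centers[placed, ] <- c(cy, cx)
      }
    }

    col0 <- matrix(seq_len(w), h, w, byrow = TRUE)
    base <- scene$backgroundLevel +
      scene$backgroundGradient * (col0 - 1) / max(1, w - 1)
    baseQ <- pmin(pmax(round(base), 0), 65535)

    added <- matrix(0, h, w)
    labels <- matrix(0L, h, w)
    truth <- data.frame(object_id = seq_len(n), population = tc$pop,
                        true_iod = NA_real_, true_area = NA_integer_)
    lambda <- 6  # texture wavelength, px
    for (i in seq_len(n)) {
      r <- radii[i]
      cy <- centers[i, 1]; cx <- centers[i, 2]
      rr <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
      cc <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
      dy <- outer(rr - cy, rep(1, length(cc)))
      dx <- outer(rep(1, length(rr)), cc - cx)
      inside <- dy^2 + dx^2 <= r^2
      npx <- sum(inside)
      icmContent <- spec$icmScale * cvNoise(tc$content[i], spec$cv)
      amp <- icmContent / npx
      tau <- scene$textureAmplitude * if (tc$pop[i] == "4N") 1.5 else 1
      tex <- 1 + tau * sin(2 * pi * outer(rr, rep(1, length(cc))) / lambda) *
                       sin(2 * pi * outer(rep(1, length(rr)), cc) / lambda)
      inc <- amp * tex
      inc[!inside] <- 0
      added[rr, cc] <- added[rr, cc] + inc
      labels[rr, cc][inside] <- i
      truth$true_area[i] <- npx
    }

    noiseFree <- pmin(pmax(round(base + added), 0), 65535)
    for (i in seq_len(n)) {
      sel <- labels == i
      truth$true_iod[i] <- sum(noiseFree[sel]) - sum(baseQ[sel])
    }
    final <- if (scene$noiseSd > 0) {
      pmin(pmax(round(base + added + rnorm(h * w, 0, scene$noiseSd)), 0), 65535)
    } else noiseFree
    list(image = LabeledImage(final, labels), truth = truth)
  })
}

#' Generate a cohort of paired samples
#'
#' Replicates a base sample specification across `nSamples` samples with
#' optional per-sample ICM intensity jitter (uniform on
#' `1 +/- icmScaleJitter`) and designated low-intensity outlier samples
#' whose `icmScale` is multiplied by `outlierScale` (modeling slides
#' bleached during digitization-parameter search). The FCM scale is held
#' fixed across the cohort: flow cytometry is the unaltered reference.
#'
#' @param nSamples number of samples.
#' @param baseSpec a [sampleSpec()] shared by all samples (per-sample
#'   seeds are derived from `baseSpec$seed`).
#' @param icmScaleJitter fraction; per-sample multiplicative jitter of
#'   `icmScale`.
#' @param outlierIndices integer indices of low-intensity outlier
#'   samples.
#' @param outlierScale multiplier (< 1) applied to the outliers'
#'   `icmScale`.
#' @return List of class `ploidyCohort`: `samples` (list of
#'   [generateEventSample()] results), `outlierTruth` (logical flags),
#'   `specs` (per-sample specifications).
#' @export
generateCohort <- function(nSamples, baseSpec = sampleSpec(),
                           icmScaleJitter = 0, outlierIndices = integer(0),
                           outlierScale = 1) {
  nSamples <- as.integer(nSamples)
  if (length(outlierIndices) &&
      (any(outlierIndices < 1) || any(outlierIndices > nSamples)))
    stop("outlierIndices out of range 1..", nSamples)
  if (length(outlierIndices) && outlierScale >= 1)
    stop("outlierScale must be < 1 for low-intensity outliers")
  seeds <- deriveSeeds(baseSpec$seed, nSamples + 1L)
  jit <- withSeed(seeds[nSamples + 1L],
                  runif(nSamples, 1 - icmScaleJitter, 1 + icmScaleJitter))
  isOut <- seq_len(nSamples) %in% outlierIndices
  specs <- lapply(seq_len(nSamples), function(i) {
    s <- baseSpec
    s$icmScale <- baseSpec$icmScale * jit[i] * if (isOut[i]) outlierScale else 1
    s$seed <- seeds[i]
    s
  })
  samples <- lapply(specs, generateEventSample)
  structure(list(samples = samples, outlierTruth = isOut, specs = specs),
            class = "ploidyCohort")
}

#' @export
print.ploidyCohort <- function(x, ...) {
  cat("ploidyCohort:", length(x$samples), "samples,",
      x$specs[[1]]$nCells, "cells each,",
      sum(x$outlierTruth), "low-intensity outlier(s)\n")
  invisible(x)
}
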