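# Cohort-level ICM -> FCM calibration: per-sample scales, naive mean
# scale, pooled linear regression with residual diagnostics, and
# intensity-outlier exclusion.

#' Per-sample ICM-to-FCM scale
#'
#' Least-squares scale through the origin mapping a sample's two ICM
#' peak locations onto its FCM peaks:
#' `s = (fcm2N * icm2N + fcm4N * icm4N) / (icm2N^2 + icm4N^2)`.
#'
#' @param icm2N,icm4N,fcm2N,fcm4N positive peak locations.
#' @return Single numeric scale.
#' @export
perSampleScale <- function(icm2N, icm4N, fcm2N, fcm4N) {
  denom <- icm2N^2 + icm4N^2
  if (denom <= 0) stop("ICM peaks must not both be zero")
  (fcm2N * icm2N + fcm4N * icm4N) / denom
}

#' Peak-ratio statistics of a cohort
#'
#' @param ratios numeric per-sample 4N/2N peak ratios (>= 2 samples).
#' @param method label carried into the output.
#' @return One-row data.frame `method`, `mean`, `sd`, `n`.
#' @export
ratioStats <- function(ratios, method = "unnamed") {
  stopifnot(length(ratios) >= 2)
  data.frame(method = method, mean = mean(ratios), sd = sd(ratios),
             n = length(ratios))
}

#' Naive cohort transfer scale
#'
#' Arithmetic mean (and sample SD) of the per-sample scales: the naive
#' single-number transfer function from ICM to FCM units.
#'
#' @param scales numeric per-sample scales (>= 2).
#' @return Named numeric `c(scale, sd)`.
#' @export
naiveTransfer <- function(scales) {
  stopifnot(length(scales) >= 2)
  c(scale = mean(scales), sd = sd(scales))
}

#' Pooled linear ICM-to-FCM regression
#'
#' Ordinary least squares `fcm = slope * icm + intercept` over pooled
#' peak points, with `RMSE = sqrt(sum(r^2) / n)`, R-squared, and a
#' Shapiro-Wilk test of residual normality.
#'
#' @param icm,fcm numeric peak coordinates (paired).
#' @param exclude logical; points to drop before fitting.
#' @return List: `slope`, `intercept`, `rmse`, `r_squared`,
#'   `shapiro_w`, `shapiro_p`, `n`, `residuals`.
#' @export
fitRegression <- function(icm, fcm, exclude = rep(FALSE, length(icm))) {
  stopifnot(length(icm) == length(fcm), length(exclude) == length(icm))
  x <- icm[!exclude]; y <- fcm[!exclude]
  if (length(x) < 3) stop("fewer than 3 points after exclusion")
  if (sd(x) == 0) stop("degenerate regression: no variance in ICM peaks")
  fit <- stats::lm(y ~ x)
  smry <- suppressWarnings(summary(fit))  # exact fits trip lm's warning
  r <- stats::residuals(fit)
  sw <- if (length(r) >= 3 && length(r) <= 5000 && sd(r) > 0)
    stats::shapiro.test(r) else list(statistic = NA_real_, p.value = NA_real_)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       rmse = sqrt(sum(r^2) / length(r)),
       r_squared = smry$r.squared,
       shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
       n = length(x), residuals = unname(r))
}

#' Flag low-intensity outlier samples
#'
#' Automatic analogue of visual-inspection exclusion: samples whose log
#' 2N ICM peak location has a modified z-score (median/MAD) below -3.5
#' are flagged as low-intensity outliers (bleached or mis-exposed
#' slides). The MAD is floored at `minSpread` (log units) so that in a
#' very homogeneous cohort sub-percent sampling fluctuations are never
#' flagged -- an outlier must be a gross intensity drop (>= ~10% below
#' the cohort at the defaults), as bleached slides are. A manual
#' exclusion list augments the automatic flags; when the raw MAD is
#' exactly zero only the manual list applies.
#'
#' @param peaks2N positive per-sample 2N ICM peak locations (>= 5).
#' @param manual integer indices to flag regardless of the rule.
#' @param minSpread floor on the MAD of log peak locations.
#' @return Logical vector of flags.
#' @export
flagIntensityOutliers <- function(peaks2N, manual = integer(0),
                                  minSpread = 0.02) {
  stopifnot(length(peaks2N) >= 5, all(peaks2N > 0))
  lp <- log(peaks2N)
  med <- median(lp)
  madRaw <- median(abs(lp - med))
  flags <- rep(FALSE, length(lp))
  if (madRaw == 0) {
    warning("MAD of log peak locations is zero; manual exclusions only")
  } else {
    mz <- 0.6745 * (lp - med) / max(madRaw, minSpread)
    flags <- mz < -3.5
  }
  flags[manual] <- TRUE
  flags
}

#' Calibrate a cohort of peak pairs
#'
#' Assembles the full cross-sample transfer function from a table of
#' per-sample ICM and FCM peak locations: per-sample scales and their
#' naive mean, pooled regressions (both nucleus peaks of every sample as
#' separate points, or 2N peaks only) with and without intensity-outlier
#' exclusion, and peak-ratio statistics per estimation method.
#'
#' @param pairs data.frame with columns `sample_id`, `method`,
#'   `icm_2N`, `icm_4N`, `fcm_2N`, `fcm_4N` (one row per sample and ICM
#'   method; `method` distinguishes e.g. bin-peak from Gaussian-fit
#'   peaks).
#' @param ratioTable optional data.frame `method`, `ratio` of
#'   per-sample peak ratios used for the ratio statistics (defaults to
#'   ratios recomputed from `pairs`).
#' @param scaleMethod which `method`'s rows drive the per-sample scales
#'   and outlier flags (default the first in `pairs`).
#' @param manualExclude integer sample indices to exclude manually.
#' @param pooling `"both_peaks"` (2 points per sample) or `"2N_only"`.
#' @return A [CohortCalibration-class].
#' @export
calibrateCohort <- function(pairs, ratioTable = NULL,
                            scaleMethod = pairs$method[1],
                            manualExclude = integer(0),
                            pooling = c("both_peaks", "2N_only")) {
  pooling <- match.arg(pooling)
  need <- c("sample_id", "method", "icm_2N", "icm_4N", "fcm_2N", "fcm_4N")
  stopifnot(all(need %in% names(pairs)))
  sp <- pairs[pairs$method == scaleMethod, , drop = FALSE]
  sp <- sp[order(sp$sample_id), , drop = FALSE]
  stopifnot(nrow(sp) >= 2)

  scales <- mapply(perSampleScale, sp$icm_2N, sp$icm_4N, sp$fcm_2N, sp$fcm_4N)
  names(scales) <- sp$sample_id
  nv <- naiveTransfer(scales)
  flags <- if (nrow(sp) >= 5) {
    flagIntensityOutliers(sp$icm_2N, manual = manualExclude)
  } else {
    # the modified z-score rule needs a cohort; small sets use the
    # manual list only
    seq_len(nrow(sp)) %in% manualExclude
  }

  fitFor <- function(sub, excludeSamples) {
    ex <- sub$sample_id %in% excludeSamples
    if (pooling == "both_peaks") {
      fitRegression(c(sub$icm_2N, sub$icm_4N), c(sub$fcm_2N, sub$fcm_4N),
                    exclude = c(ex, ex))
    } else {
      fitRegression(sub$icm_2N, sub$fcm_2N, exclude = ex)
    }
  }
  methods <- unique(pairs$method)
  regAll <- lapply(methods, function(mth)
    fitFor(pairs[pairs$method == mth, ], character(0)))
  regExcl <- lapply(methods, function(mth)
    fitFor(pairs[pairs$method == mth, ], sp$sample_id[flags]))
  names(regAll) <- names(regExcl) <- methods

  if (is.null(ratioTable)) {
    ratioTable <- do.call(rbind, lapply(methods, function(mth) {
      sub <- pairs[pairs$method == mth, ]
      data.frame(method = mth, ratio = sub$icm_4N / sub$icm_2N)
    }))
  }
  rs <- do.call(rbind, lapply(unique(ratioTable$method), function(mth)
    ratioStats(ratioTable$ratio[ratioTable$method == mth], mth)))

  new("CohortCalibration", scales = scales, naiveScale = unname(nv["scale"]),
      naiveSD = unname(nv["sd"]), regression = regAll,
      regressionExcluded = regExcl, ratioStats = rs,
      outlierFlags = as.logical(flags))
}
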