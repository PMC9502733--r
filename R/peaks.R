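# DNA-content peak estimation per population: modal histogram bin and
# fitted normal distribution. Both methods are applied identically to
# ICM integrated densities and FCM channel values, so per-sample 4N/2N
# peak ratios are comparable across modalities.

binValues <- function(values, binCount, range) {
  lo <- range[1]; hi <- range[2]
  if (!(hi > lo)) {
    # degenerate range: all mass in one notional bin at the value itself
    return(list(counts = length(values), centers = lo,
                breaks = c(lo, lo)))
  }
  breaks <- seq(lo, hi, length.out = binCount + 1)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE)
  idx <- idx[idx >= 1 & idx <= binCount]
  counts <- tabulate(idx, binCount)
  centers <- (breaks[-1] + breaks[-(binCount + 1)]) / 2
  list(counts = counts, centers = centers, breaks = breaks)
}

#' Modal-bin peak of a DNA-content histogram
#'
#' Bins the population's DNA values into `binCount` half-open bins
#' `[lo, hi)` (last bin closed) over `range` and returns the center of
#' the modal bin. Ties are resolved toward the lower bin.
#'
#' @param values numeric DNA contents of one population (>= 30 values).
#' @param binCount number of bins (default 256, an FCM-like channel
#'   resolution; must be >= 32).
#' @param range histogram range; defaults to the range of `values`
#'   (pass the whole sample's range for cross-population comparability).
#' @return One-row data.frame: `method = "bin_peak"`, `location`,
#'   `n_members`.
#' @export
histogramPeak <- function(values, binCount = 256, range = base::range(values)) {
  stopifnot(binCount >= 32)
  if (length(values) < 30)
    stop("population too small for histogram peak estimation (n = ",
         length(values), " < 30)")
  b <- binValues(values, binCount, range)
  mx <- max(b$counts)
  if (sum(b$counts == mx) > 1)
    message("modal-bin tie; resolved toward the lower bin")
  i <- which.max(b$counts)  # first maximum = lowest bin
  data.frame(method = "bin_peak", location = b$centers[i],
             n_members = length(values))
}

#' Gaussian-fit peak of a DNA-content histogram
#'
#' Least-squares fit of `A * exp(-(x - mu)^2 / (2 * sigma^2))` to the
#' population's binned counts (Levenberg-Marquardt), initialized at the
#' modal bin; returns the fitted mean as the peak location. On
#' non-convergence, falls back to the trimmed sample mean (inner 90%)
#' and flags the estimate.
#'
#' @inheritParams histogramPeak
#' @return One-row data.frame: `method = "gauss_fit"`, `location` (the
#'   fitted `mu`), `amplitude`, `mu`, `sigma`, `n_members`, `converged`.
#' @export
fitNormalPeak <- function(values, binCount = 256, range = base::range(values)) {
  stopifnot(binCount >= 32)
  if (length(values) < 30)
    stop("population too small for peak fitting (n = ", length(values),
         " < 30)")
  b <- binValues(values, binCount, range)
  i0 <- which.max(b$counts)
  start <- list(A = max(b$counts), mu = b$centers[i0],
                sigma = max(sd(values), diff(range) / binCount, 1e-12))
  df <- data.frame(x = b$centers, y = b$counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)),
                      data = df, start = start,
                      lower = c(A = 0, mu = range[1] - diff(range),
                                sigma = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("Gaussian peak fit did not converge; ",
            "falling back to the inner-90% trimmed mean")
    q <- quantile(values, c(0.05, 0.95))
    loc <- mean(values[values >= q[1] & values <= q[2]])
    return(data.frame(method = "gauss_fit", location = loc,
                      amplitude = NA_real_, mu = loc, sigma = NA_real_,
                      n_members = length(values), converged = FALSE))
  }
  cf <- coef(fit)
  data.frame(method = "gauss_fit", location = unname(cf["mu"]),
             amplitude = unname(cf["A"]), mu = unname(cf["mu"]),
             sigma = abs(unname(cf["sigma"])), n_members = length(values),
             converged = TRUE)
}

#' 4N/2N peak ratio
#'
#' Ratio of the 4N peak location to the 2N peak location of one sample
#' under one estimation method. Equals 2.0 in theory for healthy
#' samples (DNA doubles before division), and is invariant to any
#' global intensity scaling -- the property that makes it comparable
#' across instruments.
#'
#' @param p4N,p2N peak estimates: either numeric locations or one-row
#'   data.frames as returned by [histogramPeak()]/[fitNormalPeak()]
#'   (methods must then match).
#' @return Single numeric ratio.
#' @export
peakRatio <- function(p4N, p2N) {
  loc <- function(p) if (is.data.frame(p)) p$location else as.numeric(p)
  if (is.data.frame(p4N) && is.data.frame(p2N) &&
      !identical(p4N$method, p2N$method))
    stop("peak ratio requires estimates from the same method")
  l2 <- loc(p2N)
  if (l2 <= 0) stop("2N peak location must be positive")
  loc(p4N) / l2
}
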