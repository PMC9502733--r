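# Choice of the granularity operator: per-sample cluster-count
# estimation by the gap statistic in the (area, granularity) plane,
# then majority-vote fault scoring across operators.

# k-means++ seeding followed by stats::kmeans, best of `restarts`.
seededKmeans <- function(x, k, restarts = 10, iterMax = 100) {
  n <- nrow(x)
  best <- NULL
  for (r in seq_len(restarts)) {
    idx <- integer(k)
    idx[1] <- sample.int(n, 1)
    if (k > 1) {
      d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
      for (j in 2:k) {
        p <- d2 / sum(d2)
        if (!all(is.finite(p)) || sum(d2) == 0)
          idx[j] <- sample.int(n, 1)
        else
          idx[j] <- sample.int(n, 1, prob = p)
        d2 <- pmin(d2, rowSums((x - matrix(x[idx[j], ], n, ncol(x),
                                           byrow = TRUE))^2))
      }
    }
    centers <- x[idx, , drop = FALSE]
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers, iter.max = iterMax)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best))
    suppressWarnings(stats::kmeans(x, centers = min(k, n - 1),
                                   iter.max = iterMax, nstart = restarts))
  else best
}

withinDispersion <- function(x, k, restarts = 10) {
  if (k == 1) {
    sum(scale(x, scale = FALSE)^2)
  } else {
    seededKmeans(x, k, restarts = restarts)$tot.withinss
  }
}

#' Gap statistic for cluster-count selection
#'
#' Compares the log within-cluster dispersion of seeded k-means (with
#' k-means++ initialization, 10 restarts) against `B` reference datasets
#' drawn uniformly over the data's bounding box:
#' `Gap(k) = mean_b log(W*_kb) - log(W_k)`. The selected count is the
#' smallest k with `Gap(k) >= Gap(k+1) - s_{k+1}` (the one-standard-error
#' rule), falling back to `kMax` when no k satisfies it.
#'
#' @param points numeric matrix (or data.frame) of observations.
#' @param kMax largest cluster count evaluated (k = 1..kMax).
#' @param B number of reference datasets.
#' @param seed random seed; the result is deterministic for a fixed seed.
#' @return A [GapResult-class].
#' @export
gapStatistic <- function(points, kMax = 6, B = 50, seed = 1) {
  x <- as.matrix(points)
  storage.mode(x) <- "double"
  kMax <- as.integer(kMax)
  stopifnot(kMax >= 1, nrow(x) >= kMax + 1)

  if (all(apply(x, 2, function(col) diff(range(col)) == 0))) {
    warning("all points identical; best k = 1")
    return(new("GapResult", kValues = seq_len(kMax),
               gap = rep(0, kMax), sk = rep(0, kMax),
               logW = rep(-Inf, kMax), bestK = 1L))
  }

  withSeed(seed, {
    W <- vapply(seq_len(kMax), function(k) withinDispersion(x, k), 0)
    lo <- apply(x, 2, min); hi <- apply(x, 2, max)
    logWstar <- matrix(NA_real_, B, kMax)
    for (b in seq_len(B)) {
      ref <- vapply(seq_len(ncol(x)),
                    function(j) runif(nrow(x), lo[j], hi[j]),
                    numeric(nrow(x)))
      logWstar[b, ] <- log(vapply(seq_len(kMax),
                                  function(k) withinDispersion(ref, k), 0))
    }
    gap <- colMeans(logWstar) - log(W)
    sk <- apply(logWstar, 2, sd) * sqrt(1 + 1 / B)
    bestK <- kMax
    if (kMax > 1) {
      for (k in seq_len(kMax - 1)) {
        if (is.finite(gap[k]) && gap[k] >= gap[k + 1] - sk[k + 1]) {
          bestK <- k
          break
        }
      }
    } else bestK <- 1L
    new("GapResult", kValues = seq_len(kMax), gap = as.numeric(gap),
        sk = as.numeric(sk), logW = log(W), bestK = as.integer(bestK))
  })
}

#' Majority-vote fault scoring of a best-k table
#'
#' Given per-operator, per-sample selected cluster counts, computes the
#' per-sample majority (mode; ties resolved toward the smallest count),
#' match flags, each operator's match ratio and fault count, and the
#' selected operator (highest match ratio; ties broken by the fixed
#' precedence dmg > prewitt > roberts > sobel > canny).
#'
#' @param bestk integer matrix, rows = operators (rownames required),
#'   columns = samples.
#' @return List with `table` (data.frame of `operator`, `match_ratio`,
#'   `fault_count`, `n_samples`), `majority` (per-sample majority vote),
#'   `matches` (logical matrix), `selected` (operator name).
#' @export
majorityScore <- function(bestk) {
  stopifnot(is.matrix(bestk), !is.null(rownames(bestk)), nrow(bestk) >= 2)
  nS <- ncol(bestk)
  majority <- apply(bestk, 2, function(v) {
    tb <- table(v)
    winners <- as.integer(names(tb)[tb == max(tb)])
    if (length(winners) > 1)
      message("majority-vote tie; resolved toward the smallest cluster count")
    min(winners)
  })
  matches <- sweep(bestk, 2, majority, "==")
  ratio <- rowMeans(matches)
  faults <- rowSums(!matches)
  precedence <- c("dmg", "prewitt", "roberts", "sobel", "canny")
  ops <- rownames(bestk)
  ord <- order(-ratio, match(ops, precedence, nomatch = length(precedence) + 1))
  tab <- data.frame(operator = ops, match_ratio = ratio,
                    fault_count = as.integer(faults), n_samples = nS,
                    row.names = NULL)
  list(table = tab[ord, , drop = FALSE], majority = majority,
       matches = matches, selected = ops[ord[1]])
}

#' Score granularity operators across a cohort
#'
#' For every sample and operator, estimates the best cluster count by
#' [gapStatistic()] in the standardized (area, granularity) plane, then
#' applies [majorityScore()]: an operator disagreeing with the
#' per-sample majority vote incurs a fault, and the operator with the
#' highest match ratio is selected.
#'
#' @param featureTables list of per-sample feature data.frames with an
#'   `area` column and one `gran_<operator>` column per operator.
#' @param operators operators to score (default all five).
#' @param kMax,B gap-statistic parameters.
#' @param seed master seed; per-(sample, operator) sub-seeds are derived
#'   deterministically.
#' @return As [majorityScore()], plus `bestk` (the operator x sample
#'   matrix of selected counts).
#' @export
scoreOperators <- function(featureTables, operators = granularityOperators(),
                           kMax = 6, B = 50, seed = 1) {
  stopifnot(length(operators) >= 2, length(featureTables) >= 1)
  nS <- length(featureTables)
  seeds <- matrix(deriveSeeds(seed, nS * length(operators)),
                  length(operators), nS)
  bestk <- matrix(NA_integer_, length(operators), nS,
                  dimnames = list(operators, NULL))
  for (i in seq_len(nS)) {
    ft <- featureTables[[i]]
    for (j in seq_along(operators)) {
      col <- paste0("gran_", operators[j])
      if (!col %in% names(ft)) stop("missing column ", col, " in sample ", i)
      pts <- cbind(as.numeric(scale(ft$area)), as.numeric(scale(ft[[col]])))
      bestk[j, i] <- bestK(gapStatistic(pts, kMax = kMax, B = B,
                                        seed = seeds[j, i]))
    }
  }
  res <- majorityScore(bestk)
  res$bestk <- bestk
  res
}
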