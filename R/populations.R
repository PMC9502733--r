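# Population identification: fuzzy c-means over the denoised
# (area, DNA content) plane, classification-uncertainty filtering, and
# debris/2N/4N labeling by DNA-content center order.

#' Fuzzy c-means clustering
#'
#' Standard Bezdek alternating optimization:
#' `u_ij = 1 / sum_k (||x_j - v_i|| / ||x_j - v_k||)^(2/(m-1))`,
#' `v_i = sum_j u_ij^m x_j / sum_j u_ij^m`, stopping when the largest
#' center shift drops below `tol` or after `maxIter` iterations. A point
#' coinciding with a center receives membership 1 for that center.
#' Centers are initialized at k-means++-selected data points under the
#' given seed, so results are deterministic.
#'
#' @param points numeric matrix (or data.frame/vector) of observations.
#' @param c number of clusters (default 3: debris, 2N, 4N).
#' @param m fuzzifier exponent, > 1.
#' @param tol convergence tolerance on the maximum center shift, relative
#'   to the root-mean-square spread of the data (so the stopping rule is
#'   invariant to the measurement units).
#' @param maxIter iteration cap; non-convergence is reported in the
#'   result, not an error.
#' @param seed random seed for initialization.
#' @return A [FuzzyClustering-class].
#' @export
fuzzyCMeans <- function(points, c = 3, m = 2, tol = 1e-5, maxIter = 300,
                        seed = 1) {
  x <- as.matrix(points)
  storage.mode(x) <- "double"
  n <- nrow(x)
  stopifnot(n > c, m > 1)
  spread <- sqrt(mean(apply(x, 2, var)))
  tolAbs <- tol * max(spread, .Machine$double.eps)

  centers <- withSeed(seed, {
    idx <- integer(c)
    idx[1] <- sample.int(n, 1)
    if (c > 1) {
      d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
      for (j in 2:c) {
        idx[j] <- if (sum(d2) > 0) sample.int(n, 1, prob = d2 / sum(d2))
                  else sample.int(n, 1)
        d2 <- pmin(d2, rowSums((x - matrix(x[idx[j], ], n, ncol(x),
                                           byrow = TRUE))^2))
      }
    }
    x[idx, , drop = FALSE]
  })

  memb <- function(centers) {
    d2 <- vapply(seq_len(c), function(i)
      rowSums((x - matrix(centers[i, ], n, ncol(x), byrow = TRUE))^2),
      numeric(n))
    d2 <- matrix(d2, n, c)
    u <- matrix(0, n, c)
    zero <- d2 <= 0
    hasZero <- rowSums(zero) > 0
    if (any(hasZero)) {
      zr <- which(hasZero)
      u[zr, ] <- zero[zr, , drop = FALSE] / rowSums(zero[zr, , drop = FALSE])
    }
    ok <- !hasZero
    if (any(ok)) {
      w <- d2[ok, , drop = FALSE]^(-1 / (m - 1))
      u[ok, ] <- w / rowSums(w)
    }
    u
  }

  converged <- FALSE
  iter <- 0L
  u <- memb(centers)
  while (iter < maxIter) {
    iter <- iter + 1L
    um <- u^m
    newCenters <- t(um) %*% x / colSums(um)
    shift <- sqrt(max(rowSums((newCenters - centers)^2)))
    centers <- newCenters
    u <- memb(centers)
    if (shift < tolAbs) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fuzzy c-means did not converge in ", maxIter, " iterations")
  new("FuzzyClustering", centers = centers, memberships = u, m = m,
      iterations = iter, converged = converged)
}

#' Classification-uncertainty filter
#'
#' Keeps only objects whose maximum cluster membership reaches the
#' threshold; points lying between populations (uncertain class) are
#' dropped before peak estimation.
#'
#' @param clustering a [FuzzyClustering-class].
#' @param threshold membership fraction in `(1/c, 1]`.
#' @return Logical vector, TRUE for kept objects.
#' @export
filterUncertain <- function(clustering, threshold = 0.6) {
  stopifnot(is(clustering, "FuzzyClustering"))
  c <- ncol(clustering@memberships)
  if (!(threshold > 1 / c && threshold <= 1))
    stop("threshold must lie in (1/c, 1]; got ", threshold, " with c = ", c)
  apply(clustering@memberships, 1, max) >= threshold
}

#' Label clusters as debris / 2N / 4N
#'
#' Orders the three clusters by their DNA-content center coordinate and
#' labels them debris, 2N, 4N. A sanity check requires the 4N/2N center
#' ratio to lie in [1.5, 2.5]; a sample failing it is flagged as
#' mis-clustered (and should be excluded downstream) rather than
#' silently mislabeled.
#'
#' @param clustering a [FuzzyClustering-class] with exactly 3 clusters.
#' @param dnaCenters numeric, the DNA-content coordinate of each cluster
#'   center (original units).
#' @return data.frame with per-object `population` (factor debris/2N/4N),
#'   `cluster`, `max_membership`; attributes `flagged` (logical),
#'   `ratio` (4N/2N center ratio) and `populationOfCluster`.
#' @export
labelPopulations <- function(clustering, dnaCenters) {
  stopifnot(is(clustering, "FuzzyClustering"))
  u <- clustering@memberships
  if (ncol(u) != 3) stop("population labeling requires c = 3 clusters")
  stopifnot(length(dnaCenters) == 3)
  ord <- order(dnaCenters)
  popOfCluster <- character(3)
  popOfCluster[ord] <- c("debris", "2N", "4N")
  ratio <- dnaCenters[ord[3]] / dnaCenters[ord[2]]
  flagged <- !(ratio >= 1.5 && ratio <= 2.5)
  if (flagged)
    warning("4N/2N center ratio ", signif(ratio, 4),
            " outside [1.5, 2.5]; sample flagged as mis-clustered")
  cl <- max.col(u, ties.method = "first")
  res <- data.frame(
    population = factor(popOfCluster[cl],
                        levels = c("debris", "2N", "4N", "unassigned")),
    cluster = cl,
    max_membership = u[cbind(seq_len(nrow(u)), cl)])
  attr(res, "flagged") <- flagged
  attr(res, "ratio") <- ratio
  attr(res, "populationOfCluster") <- popOfCluster
  res
}
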