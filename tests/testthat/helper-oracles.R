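# Independent brute-force oracles and fixture builders. These follow the
# measurement definitions literally (full-frame pixel enumeration,
# per-pixel distance minimization) and deliberately share no code with
# the package's optimized implementations.

# Literal integrated-density oracle: enumerate every frame pixel, keep
# unlabeled pixels whose squared distance to the measured object is
# <= D^2 and whose squared distance to any object is > d^2, average
# their intensities, and subtract |O| * mean(B) from the object sum.
# Returns NA when the background set is empty.
oracleIOD <- function(int, lab, id, D, d) {
  own <- which(lab == id, arr.ind = TRUE)
  allobj <- which(lab > 0, arr.ind = TRUE)
  bg <- which(lab == 0, arr.ind = TRUE)
  if (nrow(bg) == 0) return(NA_real_)
  dOwn2 <- outer(bg[, 1], own[, 1], "-")^2 + outer(bg[, 2], own[, 2], "-")^2
  dAny2 <- outer(bg[, 1], allobj[, 1], "-")^2 +
    outer(bg[, 2], allobj[, 2], "-")^2
  keep <- apply(dOwn2, 1, min) <= D^2 & apply(dAny2, 1, min) > d^2
  if (!any(keep)) return(NA_real_)
  B <- int[bg[keep, , drop = FALSE]]
  sum(int[lab == id]) - sum(lab == id) * (sum(B) / length(B))
}

# Same enumeration, returning the sorted background intensity set.
oracleAnnulus <- function(int, lab, id, D, d) {
  own <- which(lab == id, arr.ind = TRUE)
  allobj <- which(lab > 0, arr.ind = TRUE)
  bg <- which(lab == 0, arr.ind = TRUE)
  dOwn2 <- outer(bg[, 1], own[, 1], "-")^2 + outer(bg[, 2], own[, 2], "-")^2
  dAny2 <- outer(bg[, 1], allobj[, 1], "-")^2 +
    outer(bg[, 2], allobj[, 2], "-")^2
  keep <- apply(dOwn2, 1, min) <= D^2 & apply(dAny2, 1, min) > d^2
  sort(int[bg[keep, , drop = FALSE]])
}

# Random small integer-intensity scene with disk objects.
randomScene <- function(n = 64, nObj = 3, rmax = 4) {
  lab <- matrix(0L, n, n)
  int <- matrix(sample(0:500, n * n, replace = TRUE), n, n)
  placed <- 0L
  guard <- 0L
  while (placed < nObj && guard < 200L) {
    guard <- guard + 1L
    cy <- sample(4:(n - 3), 1); cx <- sample(4:(n - 3), 1)
    r <- sample(2:rmax, 1)
    rows <- max(1, cy - r):min(n, cy + r)
    cols <- max(1, cx - r):min(n, cx + r)
    block <- lab[rows, cols]
    disk <- outer(rows - cy, rep(1, length(cols)))^2 +
      outer(rep(1, length(rows)), cols - cx)^2 <= r^2
    if (any(block[disk] != 0)) next
    placed <- placed + 1L
    block[disk] <- placed
    lab[rows, cols] <- block
  }
  LabeledImage(int, lab)
}

# Direct convolution oracle for gradient operators: plain double loop
# over object pixels with replicate border handling.
oracleGradientSum <- function(int, mask, kx, ky, erosion) {
  nr <- nrow(int); nc <- ncol(int)
  at <- function(i, j) int[min(max(i, 1), nr), min(max(j, 1), nc)]
  ax <- (nrow(kx) + 1) %/% 2; ay <- (ncol(kx) + 1) %/% 2
  total <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      # erosion check: all neighbours within the erosion square in mask
      inner <- TRUE
      for (a in -erosion:erosion) {
        for (b in -erosion:erosion) {
          ii <- i + a; jj <- j + b
          if (ii < 1 || ii > nr || jj < 1 || jj > nc || !mask[ii, jj]) {
            inner <- FALSE
            break
          }
        }
        if (!inner) break
      }
      if (!inner) next
      gx <- 0; gy <- 0
      for (a in seq_len(nrow(kx))) {
        for (b in seq_len(ncol(kx))) {
          gx <- gx + kx[a, b] * at(i + a - ax, j + b - ay)
          gy <- gy + ky[a, b] * at(i + a - ax, j + b - ay)
        }
      }
      total <- total + sqrt(gx^2 + gy^2)
    }
  }
  total
}

# Build a LabeledImage containing one disk of a given pixel count at a
# constant increment above a flat background.
diskScene <- function(n = 64, targetArea = 100, increment = 50, bg = 10) {
  r <- sqrt(targetArea / pi)
  repeat {
    cy <- cx <- (n + 1) / 2
    rows <- seq_len(n); cols <- seq_len(n)
    disk <- outer(rows - cy, rep(1, n))^2 +
      outer(rep(1, n), cols - cx)^2 <= r^2
    if (sum(disk) >= targetArea) break
    r <- r * 1.02
  }
  # trim to exactly targetArea pixels (drop farthest pixels)
  idx <- which(disk, arr.ind = TRUE)
  d2 <- (idx[, 1] - cy)^2 + (idx[, 2] - cx)^2
  keep <- idx[order(d2)[seq_len(targetArea)], , drop = FALSE]
  lab <- matrix(0L, n, n)
  lab[keep] <- 1L
  int <- matrix(bg, n, n)
  int[keep] <- bg + increment
  LabeledImage(int, lab)
}
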