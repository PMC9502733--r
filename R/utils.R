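# Internal helpers: seeded evaluation and small raster primitives.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Deterministic sub-stream seeds derived from a master seed.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Replicate-pad a matrix by r pixels on every side.
padReplicate <- function(x, r) {
  ri <- pmin(pmax(seq_len(nrow(x) + 2 * r) - r, 1L), nrow(x))
  ci <- pmin(pmax(seq_len(ncol(x) + 2 * r) - r, 1L), ncol(x))
  x[ri, ci, drop = FALSE]
}

# 2-D cross-correlation, "same" output, replicate border handling.
# anchor gives the kernel element aligned with the output pixel.
xcorr2 <- function(x, k, anchor = c((nrow(k) + 1) %/% 2, (ncol(k) + 1) %/% 2)) {
  nr <- nrow(x); nc <- ncol(x)
  r <- max(dim(k))
  xp <- padReplicate(x, r)
  out <- matrix(0, nr, nc)
  for (a in seq_len(nrow(k))) {
    for (b in seq_len(ncol(k))) {
      if (k[a, b] == 0) next
      out <- out + k[a, b] *
        xp[(r + a - anchor[1]) + seq_len(nr), (r + b - anchor[2]) + seq_len(nc)]
    }
  }
  out
}

# Min/max filter over a (2r+1)x(2r+1) square window, replicate borders.
localExtreme <- function(x, r, fun = pmax) {
  xp <- padReplicate(x, r)
  nr <- nrow(x); nc <- ncol(x)
  out <- NULL
  for (a in -r:r) {
    for (b in -r:r) {
      sh <- xp[(r + a) + seq_len(nr), (r + b) + seq_len(nc)]
      out <- if (is.null(out)) sh else fun(out, sh)
    }
  }
  out
}

# Binary erosion by a (2r+1)x(2r+1) square; outside-image counts as FALSE.
erodeSquare <- function(mask, r) {
  xp <- matrix(FALSE, nrow(mask) + 2 * r, ncol(mask) + 2 * r)
  xp[r + seq_len(nrow(mask)), r + seq_len(ncol(mask))] <- mask
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (a in -r:r)
    for (b in -r:r)
      out <- out & xp[(r + a) + seq_len(nrow(mask)),
                      (r + b) + seq_len(ncol(mask))]
  out
}

# 4-connected boundary pixels of a logical mask (any 4-neighbour outside
# the mask or outside the image). The nearest object pixel to any point
# outside the object is always such a pixel.
boundary4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  up    <- rbind(FALSE, mask[-nr, , drop = FALSE])
  down  <- rbind(mask[-1, , drop = FALSE], FALSE)
  left  <- cbind(FALSE, mask[, -nc, drop = FALSE])
  right <- cbind(mask[, -1, drop = FALSE], FALSE)
  mask & !(up & down & left & right)
}

# Minimum squared Euclidean distance from each query point to a point set.
# Exact in integer arithmetic for integer coordinates. Both arguments are
# 2-column (row, col) matrices.
minSqDist <- function(query, set) {
  if (nrow(set) == 0) return(rep(Inf, nrow(query)))
  d2 <- outer(query[, 1], set[, 1], "-")^2 + outer(query[, 2], set[, 2], "-")^2
  if (nrow(query) == 1) min(d2) else apply(d2, 1, min)
}

# Row/col coordinates of TRUE entries as a 2-column matrix.
whichCoords <- function(mask) {
  which(mask, arr.ind = TRUE)
}
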