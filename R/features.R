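#' Background annulus of an object
#'
#' Returns the intensities of the local background pixels used to
#' estimate the background level under a nucleus: pixels that belong to
#' no object, lie within Euclidean distance `D` of the measured object,
#' and are farther than `d` from every object. The proximity halo around
#' *all* objects (not just the measured one) is excluded so that
#' neighbouring nuclei never leak into each other's background estimate.
#'
#' Distances are computed exactly in integer squared-distance arithmetic
#' against the 4-connected boundary pixels of each object.
#'
#' @param image a [LabeledImage-class].
#' @param objectId positive integer label present in the mask.
#' @param cfg a [backgroundConfig()] list (radii `D` and `d`).
#' @return Numeric vector of background pixel intensities; length 0 when
#'   the annulus is empty (e.g. the object is fully enclosed by others).
#' @export
backgroundAnnulus <- function(image, objectId, cfg = backgroundConfig()) {
  stopifnot(is(image, "LabeledImage"))
  labels <- image@labels
  own <- labels == objectId
  if (!any(own)) stop("object ", objectId, " not present in label mask")
  D <- cfg$D; d <- cfg$d

  # crop wide enough that every decision (<= D to own object, > d to any
  # object) is made on complete information
  m <- ceiling(D + d) + 2L
  rc <- whichCoords(own)
  r1 <- max(1L, min(rc[, 1]) - m); r2 <- min(nrow(labels), max(rc[, 1]) + m)
  c1 <- max(1L, min(rc[, 2]) - m); c2 <- min(ncol(labels), max(rc[, 2]) + m)
  sub <- labels[r1:r2, c1:c2, drop = FALSE]

  cand <- whichCoords(sub == 0L)
  if (nrow(cand) == 0) return(numeric(0))
  ownB <- whichCoords(boundary4(sub == objectId))
  anyB <- whichCoords(boundary4(sub > 0L))

  dOwn2 <- minSqDist(cand, ownB)
  dAny2 <- minSqDist(cand, anyB)
  keep <- dOwn2 <= D^2 & dAny2 > d^2
  if (!any(keep)) return(numeric(0))
  sel <- cand[keep, , drop = FALSE]
  image@intensity[cbind(sel[, 1] + r1 - 1L, sel[, 2] + c1 - 1L)]
}

# Global fallback background: all unlabeled pixels farther than d from
# any object, over the whole frame. Used when an object's annulus is
# empty; the occurrence is reported by the caller.
globalBackground <- function(image, cfg) {
  labels <- image@labels
  cand <- whichCoords(labels == 0L)
  if (nrow(cand) == 0) return(numeric(0))
  anyB <- whichCoords(boundary4(labels > 0L))
  if (nrow(anyB) == 0) return(image@intensity[labels == 0L])
  # chunked to bound the distance-matrix size on large frames
  keep <- logical(nrow(cand))
  step <- max(1L, floor(4e6 / max(1L, nrow(anyB))))
  for (i0 in seq(1L, nrow(cand), by = step)) {
    idx <- i0:min(nrow(cand), i0 + step - 1L)
    keep[idx] <- minSqDist(cand[idx, , drop = FALSE], anyB) > cfg$d^2
  }
  image@intensity[cand[keep, , drop = FALSE]]
}

#' Background-corrected integrated density (IOD)
#'
#' DNA content of a nucleus as the integrated optical density: the sum of
#' its pixel intensities minus the object pixel count times the mean of
#' the local background annulus. Under stoichiometric PI staining this is
#' proportional to the amount of DNA. The value may be negative for a dim
#' object on a bright background and is deliberately not clipped.
#'
#' When the annulus is empty the frame-global background (unlabeled
#' pixels farther than `d` from any object) is used instead, and a
#' warning of class `cytoploidy_empty_annulus` is raised.
#'
#' @inheritParams backgroundAnnulus
#' @return A single numeric value; attributes `bkg_mean` and `bkg_n`
#'   carry the background estimate and its pixel count.
#' @export
integratedDensity <- function(image, objectId, cfg = backgroundConfig()) {
  own <- image@labels == objectId
  if (!any(own)) stop("object ", objectId, " not present in label mask")
  B <- backgroundAnnulus(image, objectId, cfg)
  if (length(B) == 0) {
    warning(warningCondition(
      paste0("empty background annulus for object ", objectId,
             "; falling back to frame-global background"),
      class = "cytoploidy_empty_annulus"))
    B <- globalBackground(image, cfg)
    if (length(B) == 0)
      stop("no background pixels available for object ", objectId)
  }
  bkg <- sum(B) / length(B)
  id <- sum(image@intensity[own]) - sum(own) * bkg
  structure(id, bkg_mean = bkg, bkg_n = length(B))
}

#' Object area in pixels
#'
#' Pixel-count area of a labeled nucleus; the image-cytometry analogue of
#' the FSC-area size measurement.
#'
#' @inheritParams backgroundAnnulus
#' @param image a [LabeledImage-class].
#' @return Integer pixel count.
#' @export
objectArea <- function(image, objectId) {
  n <- sum(image@labels == objectId)
  if (n == 0) stop("object ", objectId, " not present in label mask")
  n
}

#' Per-nucleus feature table
#'
#' Measures every labeled object: pixel area, background-corrected
#' integrated density, and granularity under each requested operator.
#' Rows are ordered by label. Failures of individual objects are recorded
#' in the `status` column and do not abort the extraction.
#'
#' @param image a [LabeledImage-class].
#' @param cfg a [backgroundConfig()].
#' @param operators character vector of granularity operators (see
#'   [granularity()]); use `character(0)` to skip granularity.
#' @return `data.frame` with columns `object_id`, `area_px`, `iod`,
#'   `bkg_mean`, `bkg_n`, one `gran_<operator>` column per operator, and
#'   `status` (`"ok"`, `"empty_annulus_fallback"`, or an error message).
#' @export
extractFeatures <- function(image, cfg = backgroundConfig(),
                            operators = granularityOperators()) {
  ids <- objectIds(image)
  if (length(ids) == 0) stop("label mask contains no objects")
  granMaps <- lapply(operators, function(op)
    granularityImage(image@intensity, op))
  names(granMaps) <- operators

  rows <- lapply(ids, function(id) {
    status <- "ok"
    iod <- withCallingHandlers(
      tryCatch(integratedDensity(image, id, cfg),
               error = function(e) { status <<- conditionMessage(e); NA_real_ }),
      cytoploidy_empty_annulus = function(w) {
        status <<- "empty_annulus_fallback"
        invokeRestart("muffleWarning")
      })
    row <- data.frame(object_id = id,
                      area_px = objectArea(image, id),
                      iod = as.numeric(iod),
                      bkg_mean = if (is.na(iod)) NA_real_
                                 else attr(iod, "bkg_mean"),
                      bkg_n = if (is.na(iod)) NA_integer_
                              else attr(iod, "bkg_n"))
    for (op in operators)
      row[[paste0("gran_", op)]] <-
        granularityFromMap(image, id, granMaps[[op]],
                           erosionRadius = granularityErosionRadius(op))
    row$status <- status
    row
  })
  do.call(rbind, rows)
}
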