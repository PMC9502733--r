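# I/O: flow-cytometry event lists (FCS 3.0 or CSV), raster images
# (TIFF/PNG), feature tables (CSV), and YAML run configuration.

#' Read a flow-cytometry event channel
#'
#' Reads one channel of an event list from an FCS 3.x list-mode file
#' (detected by its magic bytes) or a CSV table. The default channel is
#' the FSC-area channel (`fsc_area`), which carries the ploidy histogram
#' under PI staining.
#'
#' @param path file path.
#' @param channel channel / column name. For a single-column CSV without
#'   that name, the single column is used.
#' @return Numeric vector of event values.
#' @export
readEvents <- function(path, channel = "fsc_area") {
  magic <- readBin(path, "raw", 6)
  if (identical(rawToChar(magic[1:3]), "FCS")) {
    dat <- readFCS(path)
    if (!channel %in% colnames(dat))
      stop("channel '", channel, "' not in FCS file; available: ",
           paste(colnames(dat), collapse = ", "))
    return(as.numeric(dat[, channel]))
  }
  df <- utils::read.csv(path)
  if (channel %in% names(df)) return(as.numeric(df[[channel]]))
  if (ncol(df) == 1) return(as.numeric(df[[1]]))
  stop("column '", channel, "' not in CSV; available: ",
       paste(names(df), collapse = ", "))
}

# Minimal FCS 3.0 list-mode reader: HEADER offsets, TEXT keywords,
# float32/float64/int DATA segment. Covers files written by writeFCS()
# and plain single-dataset instrument exports.
readFCS <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58))
  version <- substr(header, 1, 6)
  if (!startsWith(version, "FCS3"))
    stop("unsupported FCS version: ", version)
  off <- function(a, b) as.integer(trimws(substr(header, a, b)))
  textBeg <- off(11, 18); textEnd <- off(19, 26)
  dataBeg <- off(27, 34); dataEnd <- off(35, 42)

  seek(con, textBeg)
  txt <- rawToChar(readBin(con, "raw", textEnd - textBeg + 1))
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- parts[seq(2, length(parts), 2)]
  names(kw) <- toupper(trimws(parts[seq(1, length(parts), 2)]))

  par <- as.integer(kw[["$PAR"]]); tot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(trimws(kw[["$DATATYPE"]]))
  byteord <- kw[["$BYTEORD"]]
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  if (dataBeg == 0) dataBeg <- as.integer(kw[["$BEGINDATA"]])
  if (dataEnd == 0) dataEnd <- as.integer(kw[["$ENDDATA"]])
  bits <- as.integer(kw[[paste0("$P", 1, "B")]])
  chNames <- vapply(seq_len(par), function(i) {
    nm <- kw[[paste0("$P", i, "N")]]
    if (is.null(nm) || is.na(nm)) paste0("P", i) else trimws(nm)
  }, "")

  seek(con, dataBeg)
  nvals <- par * tot
  vals <- switch(dtype,
    F = readBin(con, "numeric", nvals, size = 4, endian = endian),
    D = readBin(con, "numeric", nvals, size = 8, endian = endian),
    I = readBin(con, "integer", nvals, size = bits / 8, endian = endian,
                signed = bits > 16),
    stop("unsupported $DATATYPE: ", dtype))
  matrix(vals, nrow = tot, ncol = par, byrow = TRUE,
         dimnames = list(NULL, chNames))
}

#' Write a minimal FCS 3.0 file
#'
#' Bare-bones single-dataset writer (float32, little-endian) intended
#' for fixtures and interchange of synthetic event lists; it emits only
#' the required keywords.
#'
#' @param values numeric matrix or data.frame of events (columns =
#'   channels) or a numeric vector (single `fsc_area` channel).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFCS <- function(values, path) {
  if (is.null(dim(values)))
    values <- matrix(values, ncol = 1, dimnames = list(NULL, "fsc_area"))
  values <- as.matrix(values)
  par <- ncol(values); tot <- nrow(values)
  kw <- c("$DATATYPE", "F", "$BYTEORD", "1,2,3,4", "$MODE", "L",
          "$PAR", as.character(par), "$TOT", as.character(tot),
          "$NEXTDATA", "0")
  for (i in seq_len(par))
    kw <- c(kw, paste0("$P", i, "N"), colnames(values)[i],
            paste0("$P", i, "B"), "32", paste0("$P", i, "R"), "262144",
            paste0("$P", i, "E"), "0,0")
  text <- paste0("/", paste(kw, collapse = "/"), "/")
  textBeg <- 58
  textEnd <- textBeg + nchar(text) - 1
  dataBeg <- textEnd + 1
  dataEnd <- dataBeg + 4 * par * tot - 1
  pad <- function(x) formatC(x, width = 8)
  header <- paste0("FCS3.0    ", pad(textBeg), pad(textEnd),
                   pad(dataBeg), pad(dataEnd), pad(0), pad(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.numeric(t(values)), con, size = 4, endian = "little")
  invisible(path)
}

#' Write a LabeledImage as 16-bit TIFF rasters
#'
#' @param image a [LabeledImage-class].
#' @param intensityPath,labelPath output TIFF paths.
#' @return Invisibly, the two paths.
#' @export
writeLabeledImage <- function(image, intensityPath, labelPath) {
  stopifnot(is(image, "LabeledImage"))
  tiff::writeTIFF(image@intensity / 65535, intensityPath,
                  bits.per.sample = 16)
  tiff::writeTIFF(image@labels / 65535, labelPath, bits.per.sample = 16)
  invisible(c(intensityPath, labelPath))
}

#' Read a LabeledImage from raster files
#'
#' Reads 8/16-bit grayscale TIFF (native integer values) or PNG
#' (values rescaled from [0, 1] to 16-bit) intensity and label rasters.
#'
#' @param intensityPath,labelPath input raster paths (.tif/.tiff/.png).
#' @return A [LabeledImage-class].
#' @export
readLabeledImage <- function(intensityPath, labelPath) {
  readRaster <- function(p) {
    if (grepl("\\.png$", p, ignore.case = TRUE)) {
      round(png::readPNG(p) * 65535)
    } else {
      m <- tiff::readTIFF(p, as.is = TRUE)
      if (length(dim(m)) == 3) m <- m[, , 1]
      m
    }
  }
  LabeledImage(readRaster(intensityPath), readRaster(labelPath))
}

#' Write / read a feature or event table as CSV
#'
#' Thin wrappers fixing the column order and full numeric precision so
#' that tables round-trip bit-exactly for integer columns and to 1e-12
#' relative for floating columns.
#'
#' @param x data.frame.
#' @param path CSV path.
#' @return `readFeatureTable` returns a data.frame; `writeFeatureTable`
#'   returns `path` invisibly.
#' @export
writeFeatureTable <- function(x, path) {
  utils::write.csv(format(x, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a YAML run configuration
#'
#' Loads a YAML file and merges it over the pipeline defaults (see
#' [pipelineDefaults()]); keys mirror the function arguments of the
#' individual stages (`background.D`, `background.d`,
#' `histogram.bin_count`, `cmeans.*`, `gap.*`, `calibration.*`,
#' `synthetic.*`).
#'
#' @param path YAML file path.
#' @return Nested list of configuration values.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  mergeList(pipelineDefaults(), cfg)
}

mergeList <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- mergeList(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Write a pipeline run report as JSON
#'
#' Serializes the report of [runPipeline()] deterministically (no
#' timestamps), so identical seeded runs produce byte-identical files.
#'
#' @param report list returned by [runPipeline()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeRunReport <- function(report, path) {
  out <- unclass(report)
  out$calibration <- NULL  # S4 object; its content is already flattened
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
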