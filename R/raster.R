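#' Band-labelled raster container
#'
#' A minimal in-memory raster: a `rows x cols x bands` numeric array plus
#' band labels, the ground resolution in cm/pixel, and the value kind
#' (`"dn"` for 0-255 digital numbers of an RGB sensor, `"reflectance"`
#' for calibrated reflectance in \[0, 1\]).
#'
#' @param values Numeric array `rows x cols x bands`, or a matrix for a
#'   single-band raster.
#' @param bands Character vector of band labels, one per band. RGB digital
#'   number rasters use `"R"`, `"G"`, `"B"`; multispectral reflectance
#'   rasters use the centre wavelength in nm as a string (`"490"` ...
#'   `"950"`).
#' @param res_cm Ground resolution in cm per pixel (> 0).
#' @param kind `"dn"`, `"reflectance"`, or `"value"` for derived grids
#'   (indices, texture statistics, LAI maps) with no range constraint.
#' @return An object of class `"lai_raster"`.
#' @examples
#' r <- lai_raster(matrix(runif(12), 3, 4), "680", res_cm = 8,
#'                 kind = "reflectance")
#' dim(r)
#' @export
lai_raster <- function(values, bands, res_cm,
                       kind = c("reflectance", "dn", "value")) {
  kind <- match.arg(kind)
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a matrix or a rows x cols x bands array")
  bands <- as.character(bands)
  if (length(bands) != dim(values)[3L])
    stop("band count (", dim(values)[3L], ") does not match label count (",
         length(bands), ")")
  if (anyDuplicated(bands)) stop("band labels must be unique")
  if (!is.numeric(res_cm) || length(res_cm) != 1L || !is.finite(res_cm) ||
      res_cm <= 0)
    stop("`res_cm` must be a single positive number")
  if (kind == "reflectance") {
    rng <- range(values, finite = TRUE)
    if (rng[1L] < 0 || rng[2L] > 1)
      stop("reflectance values must lie in [0, 1]")
  }
  structure(list(values = values, bands = bands, res_cm = as.numeric(res_cm),
                 kind = kind),
            class = "lai_raster")
}

#' @export
dim.lai_raster <- function(x) dim(x$values)

#' @export
print.lai_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<lai_raster> %d x %d px, %d band(s) [%s], %g cm/px, %s\n",
              d[1L], d[2L], d[3L], paste(x$bands, collapse = ","),
              x$res_cm, x$kind))
  invisible(x)
}

#' Extract one band of a raster as a matrix
#'
#' @param raster A [lai_raster].
#' @param band Band label (character) or index.
#' @return A numeric matrix.
#' @export
get_band <- function(raster, band) {
  stopifnot(inherits(raster, "lai_raster"))
  if (is.character(band)) {
    i <- match(band, raster$bands)
    if (is.na(i)) stop("band '", band, "' not present; have: ",
                       paste(raster$bands, collapse = ", "))
  } else i <- as.integer(band)
  raster$values[, , i, drop = TRUE]
}

#' Keep a subset of bands
#'
#' @inheritParams get_band
#' @param bands Character vector of band labels to retain (order kept).
#' @return A [lai_raster] with only those bands.
#' @export
select_bands <- function(raster, bands) {
  stopifnot(inherits(raster, "lai_raster"))
  i <- match(as.character(bands), raster$bands)
  if (anyNA(i)) stop("unknown band(s): ",
                     paste(bands[is.na(i)], collapse = ", "))
  lai_raster(raster$values[, , i, drop = FALSE], raster$bands[i],
             raster$res_cm, raster$kind)
}

# Lossless packing of a double matrix into 16-bit TIFF samples: the 8 bytes
# of each float64 become four uint16 words, stacked along the row axis, so
# the round trip through the fixed-point TIFF writer is bit-exact.
.pack_f64 <- function(m) {
  raw <- writeBin(as.vector(m), raw(), size = 8L, endian = "little")
  u16 <- readBin(raw, "integer", n = 4L * length(m), size = 2L,
                 signed = FALSE, endian = "little")
  matrix(u16, nrow = 4L * nrow(m), ncol = ncol(m))
}

.unpack_f64 <- function(u16m, n_rows) {
  raw <- writeBin(as.integer(u16m), raw(), size = 2L, endian = "little")
  vals <- readBin(raw, "double", n = length(u16m) / 4L, size = 8L,
                  endian = "little")
  matrix(vals, nrow = n_rows)
}

.sidecar_path <- function(path) paste0(path, ".json")

#' Write a raster to disk
#'
#' The grid goes into a multi-page TIFF (one page per band) and the band
#' labels, resolution and value kind into a JSON sidecar next to it. DN
#' rasters are stored as 8-bit samples; reflectance rasters are packed
#' losslessly (float64 bytes as 16-bit samples), so the write/read round
#' trip preserves values bit-exactly for both kinds.
#'
#' @param raster A [lai_raster].
#' @param path Output path (conventionally `.tif`); the sidecar is written
#'   to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "lai_raster"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  d <- dim(raster$values)
  if (raster$kind == "dn") {
    v <- raster$values
    if (any(v < 0 | v > 255, na.rm = TRUE) ||
        any(v != round(v), na.rm = TRUE))
      stop("dn raster values must be integers in 0..255")
    pages <- lapply(seq_len(d[3L]), function(b) raster$values[, , b] / 255)
    bits <- 8L
    encoding <- "dn8"
  } else {
    pages <- lapply(seq_len(d[3L]),
                    function(b) .pack_f64(raster$values[, , b]) / 65535)
    bits <- 16L
    encoding <- "float64-packed16"
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits,
                  compression = "deflate", reduce = FALSE)
  meta <- list(bands = raster$bands, res_cm = raster$res_cm,
               kind = raster$kind, encoding = encoding,
               n_rows = d[1L], n_cols = d[2L])
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raster written by [write_raster]
#'
#' @param path Path to the TIFF file.
#' @param sensor_hint Optional; if the sidecar is missing and the file has
#'   three unlabelled pages, `"rgb"` assigns labels `R`, `G`, `B` and kind
#'   `"dn"`.
#' @return A [lai_raster].
#' @export
read_raster <- function(path, sensor_hint = NULL) {
  if (!file.exists(path)) stop("cannot read raster, no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- .sidecar_path(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (identical(meta$encoding, "float64-packed16")) {
      mats <- lapply(pages, .unpack_f64, n_rows = meta$n_rows)
    } else {
      mats <- pages
    }
    v <- array(unlist(mats, use.names = FALSE),
               c(nrow(mats[[1L]]), ncol(mats[[1L]]), length(mats)))
    if (length(meta$bands) != length(mats))
      stop("band count (", length(mats), ") does not match label count (",
           length(meta$bands), ") in ", side)
    return(lai_raster(v, meta$bands, meta$res_cm, meta$kind))
  }
  if (identical(sensor_hint, "rgb") && length(pages) == 3L) {
    v <- array(unlist(pages, use.names = FALSE),
               c(nrow(pages[[1L]]), ncol(pages[[1L]]), 3L))
    return(lai_raster(v, c("R", "G", "B"), res_cm = 1, kind = "dn"))
  }
  stop("missing band labels for ", path,
       " (no sidecar ", side, " and no usable sensor hint)")
}

#' Crop a raster to a plot window
#'
#' Windows are 0-based, half-open pixel ranges: the window covers rows
#' `row0 .. row0 + n_rows - 1` and likewise for columns.
#'
#' @param raster A [lai_raster].
#' @param roi A list or one-row data frame with fields `row0`, `col0`,
#'   `n_rows`, `n_cols` (see [generate_dataset] for the plot ROI table).
#' @return The sub-raster; resolution and band labels are preserved.
#' @export
crop_plot <- function(raster, roi) {
  stopifnot(inherits(raster, "lai_raster"))
  r0 <- as.integer(roi$row0); c0 <- as.integer(roi$col0)
  nr <- as.integer(roi$n_rows); nc <- as.integer(roi$n_cols)
  d <- dim(raster$values)
  if (nr < 1L || nc < 1L) stop("window must span at least one pixel")
  if (r0 < 0L || c0 < 0L || r0 + nr > d[1L] || c0 + nc > d[2L])
    stop(sprintf("window [%d,%d)x[%d,%d) out of raster bounds %dx%d",
                 r0, r0 + nr, c0, c0 + nc, d[1L], d[2L]))
  lai_raster(raster$values[(r0 + 1L):(r0 + nr), (c0 + 1L):(c0 + nc), ,
                           drop = FALSE],
             raster$bands, raster$res_cm, raster$kind)
}
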