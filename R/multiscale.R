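#' Default resolution ladders
#'
#' The coarsening ladders used throughout: 1-48 cm for the RGB sensor,
#' 8-48 cm for the multispectral sensor.
#'
#' @param sensor `"rgb"` or `"mca"`.
#' @return Numeric vector of resolutions in cm/pixel, strictly increasing.
#' @export
resolution_ladder <- function(sensor = c("rgb", "mca")) {
  sensor <- match.arg(sensor)
  if (sensor == "rgb") c(1, 4, 8, 16, 24, 32, 40, 48) else
    c(8, 16, 24, 32, 40, 48)
}

# Pixel-centre nearest-neighbour index map: output index d (0-based) takes
# source index floor((d + 0.5) * target / native), clipped to bounds.
.nn_index <- function(n_out, target, native, n_in) {
  s <- floor(((seq_len(n_out) - 0.5)) * target / native)
  pmin(pmax(s, 0), n_in - 1L) + 1L  # 1-based for R indexing
}

#' Nearest-neighbour resampling to a coarser resolution
#'
#' Each target pixel centre is mapped back into the source grid and takes
#' the value of the nearest source pixel, so every output value occurs in
#' the input. Only coarsening is supported.
#'
#' @param raster A [lai_raster].
#' @param target_cm Target resolution in cm/pixel (`>=` native).
#' @return A [lai_raster] at `target_cm` with shape
#'   `floor(extent / target)` per axis.
#' @export
resample_nearest <- function(raster, target_cm) {
  stopifnot(inherits(raster, "lai_raster"))
  native <- raster$res_cm
  if (target_cm < native)
    stop("upsampling not supported: target ", target_cm,
         " cm is finer than native ", native, " cm")
  if (target_cm == native) return(raster)
  d <- dim(raster$values)
  n_out_r <- as.integer(floor(d[1L] * native / target_cm))
  n_out_c <- as.integer(floor(d[2L] * native / target_cm))
  if (n_out_r < 1L || n_out_c < 1L)
    stop("target resolution coarser than the raster extent")
  ir <- .nn_index(n_out_r, target_cm, native, d[1L])
  ic <- .nn_index(n_out_c, target_cm, native, d[2L])
  lai_raster(raster$values[ir, ic, , drop = FALSE], raster$bands,
             target_cm, raster$kind)
}

#' Resample a raster to every rung of a ladder
#'
#' Every rung is produced directly from the native raster (never chained
#' through intermediate scales).
#'
#' @param raster A [lai_raster] at native resolution.
#' @param ladder Strictly increasing resolutions, each `>=` native.
#' @return Named list of rasters, names are the resolutions in cm.
#' @export
build_ladder <- function(raster, ladder = resolution_ladder("mca")) {
  stopifnot(inherits(raster, "lai_raster"))
  if (any(diff(ladder) <= 0)) stop("ladder must be strictly increasing")
  if (any(ladder < raster$res_cm))
    stop("ladder contains resolutions finer than native")
  out <- lapply(ladder, function(t) resample_nearest(raster, t))
  names(out) <- as.character(ladder)
  out
}

#' Map a plot window onto a coarser grid
#'
#' The native window is carried through the same index mapping as
#' [resample_nearest]: the coarse window consists of the coarse pixels
#' whose nearest-neighbour source lies inside the native window, then
#' shrinks by `shrink` coarse pixels on every side to drop mixed border
#' pixels. Returns `NULL` when the shrunken window vanishes.
#'
#' @param roi A list/row with `row0, col0, n_rows, n_cols` at native scale.
#' @param native_cm,target_cm Native and target resolutions in cm/pixel.
#' @param shrink Border pixels to drop on each side at the coarse scale.
#' @return A list with the coarse `row0, col0, n_rows, n_cols` (plus any
#'   label fields of `roi`), or `NULL`.
#' @export
roi_at_scale <- function(roi, native_cm, target_cm, shrink = 1L) {
  if (target_cm < native_cm) stop("target must be >= native resolution")
  f <- target_cm / native_cm
  # coarse pixel d maps to source floor((d+0.5) f); keep d whose source
  # falls inside [row0, row0+n)
  rng <- function(a0, n) {
    d_lo <- ceiling(a0 / f - 0.5 - 1e-9)         # d >= a0/f - 1/2
    d_hi <- ceiling((a0 + n) / f - 0.5 - 1e-9) - 1  # d < (a0+n)/f - 1/2
    c(d_lo, d_hi)
  }
  rr <- rng(roi$row0, roi$n_rows); cc <- rng(roi$col0, roi$n_cols)
  rr <- rr + c(shrink, -shrink); cc <- cc + c(shrink, -shrink)
  if (rr[1L] > rr[2L] || cc[1L] > cc[2L]) return(NULL)
  out <- as.list(roi)
  out$row0 <- as.integer(rr[1L]); out$col0 <- as.integer(cc[1L])
  out$n_rows <- as.integer(rr[2L] - rr[1L] + 1L)
  out$n_cols <- as.integer(cc[2L] - cc[1L] + 1L)
  out
}
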