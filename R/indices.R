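#' Chromatic coordinates from RGB digital numbers
#'
#' `r = R/(R+G+B)` etc., vectorised. Where `R+G+B = 0` the coordinates are
#' the `NaN` fill value.
#'
#' @param R,G,B Nonnegative digital numbers (scalars or arrays).
#' @return List with components `r`, `g`, `b` summing to 1 where defined.
#' @export
chromatic_coords <- function(R, G, B) {
  tot <- R + G + B
  tot[tot == 0] <- NaN
  list(r = R / tot, g = G / tot, b = B / tot)
}

.mca_wavelengths <- c(490, 520, 550, 570, 670, 680, 700, 720, 800, 850,
                      900, 950)

# One entry per spectral index: name is the feature-table column key,
# sensor selects the band vocabulary, fun evaluates on a named list of
# band values (DN for rgb, reflectance keyed "R490".."R950" for mca).
.si_defs <- local({
  rgb_fun <- function(expr) {
    f <- function(v) NULL
    body(f) <- substitute({
      cc <- chromatic_coords(v$R, v$G, v$B)
      r <- cc$r; g <- cc$g; b <- cc$b
      e
    }, list(e = expr))
    f
  }
  defs <- list(
    list(name = "R", sensor = "rgb", fun = function(v) v$R),
    list(name = "G", sensor = "rgb", fun = function(v) v$G),
    list(name = "B", sensor = "rgb", fun = function(v) v$B),
    list(name = "r", sensor = "rgb", fun = rgb_fun(quote(r))),
    list(name = "g", sensor = "rgb", fun = rgb_fun(quote(g))),
    list(name = "b", sensor = "rgb", fun = rgb_fun(quote(b))),
    list(name = "ExR", sensor = "rgb", fun = rgb_fun(quote(1.4 * r - g))),
    list(name = "ExG", sensor = "rgb",
         fun = rgb_fun(quote(2 * g - r - b))),
    list(name = "ExB", sensor = "rgb", fun = rgb_fun(quote(1.4 * b - g))),
    list(name = "ExG_ExR", sensor = "rgb",
         fun = rgb_fun(quote(3 * g - 2.4 * r - b))),
    list(name = "VARI_rgb", sensor = "rgb",
         fun = rgb_fun(quote((g - r) / (g + r - b)))),
    list(name = "GRVI", sensor = "rgb",
         fun = rgb_fun(quote((g - r) / (g + r))))
  )
  for (wl in .mca_wavelengths) {
    defs[[length(defs) + 1L]] <-
      list(name = paste0("R", wl), sensor = "mca",
           fun = local({ key <- paste0("R", wl); function(v) v[[key]] }))
  }
  mca <- list(
    NDVI = function(v) (v$R800 - v$R670) / (v$R800 + v$R670),
    NDRE = function(v) (v$R800 - v$R720) / (v$R800 + v$R720),
    EVI2 = function(v) 2.5 * (v$R800 - v$R670) /
      (v$R800 + 2.4 * v$R670 + 1),
    GNDVI = function(v) (v$R800 - v$R550) / (v$R800 + v$R550),
    CI_rededge = function(v) v$R800 / v$R720 - 1,
    CI_green = function(v) v$R800 / v$R550 - 1,
    VARI_mca = function(v) (v$R550 - v$R670) / (v$R550 + v$R670),
    OSAVI = function(v) 1.16 * (v$R800 - v$R670) /
      (v$R800 + v$R670 + 0.16)
  )
  for (nm in names(mca))
    defs[[length(defs) + 1L]] <- list(name = nm, sensor = "mca",
                                      fun = mca[[nm]])
  defs
})

#' Names of the registered spectral indices
#'
#' Twelve RGB features (band digital numbers, chromatic coordinates and
#' the excess-colour family) and twenty multispectral features (the twelve
#' band reflectances plus eight vegetation indices). The VARI definitions
#' differ between sensors, hence the sensor-qualified keys.
#'
#' @param sensor `"rgb"`, `"mca"` or `"all"`.
#' @return Character vector of registry keys.
#' @export
si_names <- function(sensor = c("all", "rgb", "mca")) {
  sensor <- match.arg(sensor)
  keep <- vapply(.si_defs, function(d)
    sensor == "all" || d$sensor == sensor, logical(1))
  vapply(.si_defs[keep], `[[`, character(1), "name")
}

.si_lookup <- function(name) {
  for (d in .si_defs) if (d$name == name) return(d)
  stop("unknown spectral index: ", name)
}

# Named band-value list from a raster or named vector.
.band_values <- function(x, sensor) {
  if (inherits(x, "lai_raster")) {
    v <- lapply(seq_along(x$bands), function(i) x$values[, , i])
    names(v) <- if (sensor == "mca") paste0("R", x$bands) else x$bands
    v
  } else {
    v <- as.list(x)
    if (sensor == "mca" && !any(grepl("^R\\d", names(v))))
      names(v) <- paste0("R", names(v))
    v
  }
}

#' Evaluate one spectral index
#'
#' @param name Registry key (see [si_names]).
#' @param bands A [lai_raster] or a named vector/list of band values: DN
#'   keyed `R`, `G`, `B` for the RGB sensor; reflectance keyed `"490"` ...
#'   `"950"` (or `"R490"` ...) for the multispectral sensor.
#' @return The index value(s); division by zero yields the `NaN` fill
#'   value with a warning.
#' @export
compute_index <- function(name, bands) {
  d <- .si_lookup(name)
  v <- .band_values(bands, d$sensor)
  out <- d$fun(v)
  bad <- is.nan(out) | is.infinite(out)
  if (any(bad)) {
    warning("index ", name, " undefined (zero denominator) for ",
            sum(bad), " value(s); filled with NaN")
    out[bad] <- NaN
  }
  out
}

#' Per-pixel spectral-index raster
#'
#' @param raster A [lai_raster] of the matching sensor.
#' @param name Registry key.
#' @return A single-band [lai_raster] (kind `"reflectance"` semantics do
#'   not apply; values are the raw index, stored unclipped).
#' @export
si_raster <- function(raster, name) {
  .si_lookup(name)  # fail early on unknown names
  vals <- compute_index(name, raster)
  lai_raster(array(vals, c(dim(raster$values)[1:2], 1L)), name,
             raster$res_cm, kind = "value")
}

#' Per-plot spectral-index table
#'
#' For every plot and stage, band values are averaged over the plot window
#' first and every registered index of the sensor is evaluated on those
#' means (`mode = "plot_mean"`, the default), or evaluated per pixel and
#' then averaged (`mode = "pixel_mean"`).
#'
#' @param rasters_by_stage Named list `stage -> lai_raster`.
#' @param rois Plot ROI table (`plot_id, row0, col0, n_rows, n_cols`, plus
#'   optional label columns carried through).
#' @param sensor `"rgb"` or `"mca"`.
#' @param truth Optional ground truth (`plot_id, stage, lai`) merged in.
#' @param mode Aggregation order.
#' @return Data frame: `plot_id, stage` (+ labels, `lai`) then one column
#'   per index.
#' @export
plot_si_table <- function(rasters_by_stage, rois,
                          sensor = c("mca", "rgb"), truth = NULL,
                          mode = c("plot_mean", "pixel_mean")) {
  sensor <- match.arg(sensor); mode <- match.arg(mode)
  nms <- si_names(sensor)
  recs <- list()
  for (st in names(rasters_by_stage)) {
    ras <- rasters_by_stage[[st]]
    if (is.null(ras)) { warning("stage ", st, " missing; skipped"); next }
    for (i in seq_len(nrow(rois))) {
      sub <- crop_plot(ras, rois[i, ])
      if (mode == "plot_mean") {
        bv <- apply(sub$values, 3L, mean)
        names(bv) <- sub$bands
        vals <- vapply(nms, function(nm)
          as.numeric(compute_index(nm, .band_values(bv, sensor))),
          numeric(1))
      } else {
        vals <- vapply(nms, function(nm)
          mean(compute_index(nm, sub), na.rm = TRUE), numeric(1))
      }
      rec <- data.frame(plot_id = rois$plot_id[i], stage = st)
      for (lab in intersect(c("treatment", "variety"), names(rois)))
        rec[[lab]] <- rois[[lab]][i]
      recs[[length(recs) + 1L]] <- cbind(rec, as.data.frame(as.list(vals)))
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  if (!is.null(truth))
    out <- merge(truth[, c("plot_id", "stage", "lai")], out,
                 by = c("plot_id", "stage"), sort = TRUE)
  out
}
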