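#' @importFrom stats rnorm approx cor sd coef lm pt quantile
NULL

#' Run code under a seed without disturbing the caller's RNG state
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a deterministic sub-stream seed from a master seed
#'
#' Mixes the master seed with one or more integer stream indices so that
#' independent pipeline stages draw from distinct, reproducible streams.
#'
#' @param seed Master integer seed.
#' @param ... Integer stream indices.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in seq_along(ix))
    s <- (s * 31 + as.double(ix[k]) * 7919 + 13) %% 2147483647
  as.integer(s)
}

#' Growth stages of the acquisition campaign
#' @export
lai_stages <- function() c("jointing", "booting", "heading")

# Piecewise-linear green-leaf reflectance: blue/red absorption troughs,
# green bump, red edge, NIR plateau.
.leaf_curve <- function(wl) {
  pts_wl <- c(400, 470, 490, 520, 550, 570, 650, 670, 680, 700, 720,
              800, 850, 900, 950, 1000)
  pts_rf <- c(0.05, 0.05, 0.05, 0.08, 0.13, 0.12, 0.06, 0.04, 0.04, 0.12,
              0.30, 0.50, 0.50, 0.49, 0.48, 0.48)
  approx(pts_wl, pts_rf, xout = wl, rule = 2)$y
}

#' Default leaf and soil spectra per sensor
#'
#' Leaf reflectance follows a piecewise-linear green-vegetation curve
#' (chlorophyll troughs at blue and 670-680 nm, green bump at 550 nm, red
#' edge, NIR plateau at 0.48-0.50); soil is spectrally flat at 0.20,
#' intermediate between the leaf troughs and the NIR plateau. RGB bands are
#' taken at 470/550/650 nm effective wavelengths.
#'
#' @param sensor `"rgb"` or `"mca"`.
#' @return A list with `bands` (labels), `leaf` and `soil` (reflectance per
#'   band, in \[0, 1\]).
#' @export
default_spectra <- function(sensor = c("rgb", "mca")) {
  sensor <- match.arg(sensor)
  if (sensor == "rgb") {
    wl <- c(R = 650, G = 550, B = 470)
    list(bands = c("R", "G", "B"), leaf = unname(.leaf_curve(wl)),
         soil = rep(0.20, 3L))
  } else {
    wl <- c(490, 520, 550, 570, 670, 680, 700, 720, 800, 850, 900, 950)
    list(bands = as.character(wl), leaf = unname(.leaf_curve(wl)),
         soil = rep(0.20, 12L))
  }
}

#' Canopy scene parameters
#'
#' Defaults encode the emulated trial: rice rows every 30 cm along the
#' plot's long axis, Beer-law light extinction `k = 0.6`, raised-cosine
#' within-plot cover modulation, stage mean LAI 1.5 / 3.5 / 5.5 at
#' jointing / booting / heading with plot-to-plot standard deviation 0.3,
#' fertilizer treatments T1 (none, lowest canopy) through T10 scaling the
#' stage mean, and additive Gaussian reflectance noise of sd 0.01.
#'
#' @param row_spacing_cm Crop row spacing in cm.
#' @param k Beer-law extinction coefficient (> 0).
#' @param mod_depth Relative amplitude of the raised-cosine row profile
#'   (0 = no rows, < 1 keeps local LAI positive).
#' @param stage_lai_mean Named numeric, mean LAI per stage (must increase
#'   from jointing to heading).
#' @param stage_lai_sd Plot-to-plot LAI standard deviation (>= 0),
#'   recycled over stages.
#' @param treatment_factor Named multiplier of the stage mean per
#'   fertilizer treatment.
#' @param noise_sd Reflectance noise standard deviation.
#' @param leaf_vis_sd,leaf_nir_sd Lognormal sd of the per-plot, per-stage
#'   multiplicative factor on leaf reflectance in the visible (< 750 nm)
#'   and NIR bands. These emulate fertilizer-driven differences in leaf
#'   optical properties, the main reason spectral indices lose sensitivity
#'   once the canopy closes: at high LAI a pixel sees only leaf, so its
#'   reflectance varies with leaf quality rather than with LAI.
#' @param soil_sd Lognormal sd of the per-plot, per-stage soil brightness
#'   factor (standing-water/soil wetness differences).
#' @param stage_leaf_vis,stage_leaf_nir Named deterministic multipliers of
#'   the effective foliage visible / NIR reflectance per stage. They
#'   emulate phenology: at heading, emerged panicles (bright in the
#'   visible) overlay the canopy and the lowest leaves begin to senesce,
#'   raising effective visible reflectance and lowering NIR relative to
#'   booting, while young jointing canopies are slightly darker in the
#'   visible. Vegetation indices therefore plateau or fall between booting
#'   and heading even though LAI keeps rising, so pooled multi-period
#'   index-LAI correlations fall below single-period ones.
#' @param base_res_cm Named numeric: native resolution per sensor.
#' @param film_reflectance Reflectance of the black separator film strips.
#' @param spectra List with `rgb` and `mca` entries as returned by
#'   [default_spectra].
#' @return A list of class `"canopy_scene_params"`.
#' @export
scene_params <- function(row_spacing_cm = 30, k = 0.6, mod_depth = 0.8,
                         stage_lai_mean = c(jointing = 1.5, booting = 3.5,
                                            heading = 5.5),
                         stage_lai_sd = 0.3,
                         treatment_factor = c(T1 = 0.65, T2 = 1.25,
                                              T3 = 0.75, T4 = 0.85,
                                              T5 = 0.90, T6 = 0.95,
                                              T7 = 1.00, T8 = 1.05,
                                              T9 = 1.10, T10 = 1.20),
                         noise_sd = 0.01,
                         leaf_vis_sd = 0.15, leaf_nir_sd = 0.06,
                         soil_sd = 0.05,
                         stage_leaf_vis = c(jointing = 0.95, booting = 1.00,
                                            heading = 1.45),
                         stage_leaf_nir = c(jointing = 1.03, booting = 1.00,
                                            heading = 0.90),
                         base_res_cm = c(rgb = 1, mca = 8),
                         film_reflectance = 0.02,
                         spectra = list(rgb = default_spectra("rgb"),
                                        mca = default_spectra("mca"))) {
  if (k <= 0) stop("extinction coefficient k must be positive")
  if (row_spacing_cm <= 0) stop("row spacing must be positive")
  if (mod_depth < 0 || mod_depth >= 1)
    stop("mod_depth must be in [0, 1)")
  if (any(stage_lai_sd < 0)) stop("stage_lai_sd must be >= 0")
  st <- lai_stages()
  if (!all(st %in% names(stage_lai_mean)))
    stop("stage_lai_mean needs entries for ", paste(st, collapse = ", "))
  m <- stage_lai_mean[st]
  if (any(diff(m) <= 0))
    stop("stage mean LAI must increase from jointing to heading")
  for (s in names(spectra)) {
    sp <- spectra[[s]]
    if (any(sp$leaf < 0 | sp$leaf > 1) || any(sp$soil < 0 | sp$soil > 1))
      stop("spectra must lie in [0, 1]")
    if (length(sp$leaf) != length(sp$bands) ||
        length(sp$soil) != length(sp$bands))
      stop("spectra and band labels disagree for sensor ", s)
  }
  if (leaf_vis_sd < 0 || leaf_nir_sd < 0 || soil_sd < 0)
    stop("spectral-factor sds must be >= 0")
  if (!all(st %in% names(stage_leaf_vis)) ||
      !all(st %in% names(stage_leaf_nir)))
    stop("stage leaf factors need entries for ", paste(st, collapse = ", "))
  structure(list(row_spacing_cm = row_spacing_cm, k = k,
                 mod_depth = mod_depth, stage_lai_mean = m,
                 stage_lai_sd = rep_len(stage_lai_sd, length(st)),
                 treatment_factor = treatment_factor, noise_sd = noise_sd,
                 leaf_vis_sd = leaf_vis_sd, leaf_nir_sd = leaf_nir_sd,
                 soil_sd = soil_sd,
                 stage_leaf_vis = stage_leaf_vis[st],
                 stage_leaf_nir = stage_leaf_nir[st],
                 base_res_cm = base_res_cm,
                 film_reflectance = film_reflectance, spectra = spectra),
            class = "canopy_scene_params")
}

#' Build the field layout
#'
#' Plots are placed on a grid separated by film-strip buffers; the grid
#' shape is the factor pair of `n_plots` giving the squarest scene. Plot
#' long axes (and hence crop rows) run along image columns, so the
#' direction perpendicular to the rows is the image row axis.
#'
#' @param n_plots Number of plots.
#' @param plot_w_m Plot extent along the row direction (columns), metres.
#' @param plot_h_m Plot extent across the rows (image rows), metres.
#' @param buffer_cm Width of the separator strips, cm.
#' @return A list of class `"field_layout"` with plot origins in cm.
#' @export
build_layout <- function(n_plots = 72, plot_w_m = 8, plot_h_m = 4,
                         buffer_cm = 48) {
  if (n_plots < 1 || plot_w_m <= 0 || plot_h_m <= 0 || buffer_cm < 0)
    stop("layout sizes must be positive")
  n_plots <- as.integer(n_plots)
  pr <- plot_h_m * 100  # cm along image rows
  pc <- plot_w_m * 100  # cm along image columns
  divs <- which(n_plots %% seq_len(n_plots) == 0L)
  gr <- divs[which.min(abs((divs * pr + (divs + 1) * buffer_cm) -
                           ((n_plots / divs) * pc +
                            (n_plots / divs + 1) * buffer_cm)))]
  gc <- n_plots %/% gr
  ids <- seq_len(n_plots)
  gi <- (ids - 1L) %/% gc  # grid row
  gj <- (ids - 1L) %% gc   # grid col
  origins <- data.frame(
    plot_id = ids,
    row0_cm = buffer_cm + gi * (pr + buffer_cm),
    col0_cm = buffer_cm + gj * (pc + buffer_cm))
  structure(list(n_plots = n_plots, grid = c(rows = gr, cols = gc),
                 plot_rows_cm = pr, plot_cols_cm = pc, buffer_cm = buffer_cm,
                 scene_rows_cm = gr * pr + (gr + 1) * buffer_cm,
                 scene_cols_cm = gc * pc + (gc + 1) * buffer_cm,
                 origins = origins),
            class = "field_layout")
}

#' Plot windows of a layout at a given resolution
#'
#' @param layout A [build_layout] result.
#' @param res_cm Pixel size in cm.
#' @return Data frame `plot_id, row0, col0, n_rows, n_cols` with 0-based,
#'   half-open pixel windows.
#' @export
layout_rois <- function(layout, res_cm) {
  stopifnot(inherits(layout, "field_layout"), res_cm > 0)
  o <- layout$origins
  data.frame(plot_id = o$plot_id,
             row0 = as.integer(floor(o$row0_cm / res_cm)),
             col0 = as.integer(floor(o$col0_cm / res_cm)),
             n_rows = as.integer(floor(layout$plot_rows_cm / res_cm)),
             n_cols = as.integer(floor(layout$plot_cols_cm / res_cm)))
}

.assign_treatments <- function(n_plots)
  rep_len(paste0("T", 1:10), n_plots)

.assign_varieties <- function(n_plots)
  rep_len(c("FY4", "FYX1"), n_plots)

# Vectorised zero-truncated normal via rejection.
.rtruncnorm0 <- function(n, mean, sd) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < 0)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    out[bad] <- rnorm(length(bad), mean[bad], if (length(sd) > 1L)
      sd[bad] else sd)
    bad <- bad[out[bad] < 0]
    guard <- guard + 1L
  }
  pmax(out, 0)
}

#' Sample ground-truth LAI per plot and stage
#'
#' Each plot's LAI is drawn from a zero-truncated normal whose mean is the
#' stage mean scaled by the plot's fertilizer-treatment factor. With
#' `stage_lai_sd = 0` every plot takes its treatment-stage mean exactly.
#' Alongside the LAI, per-plot multiplicative spectral factors are drawn
#' (lognormal, mean 1): `vis_factor` and `nir_factor` on leaf reflectance
#' and `soil_factor` on soil brightness (see [scene_params]); [render_scene]
#' applies them, and treats them as 1 when absent.
#'
#' @param layout A [build_layout] result.
#' @param params A [scene_params] object.
#' @param seed Integer seed; identical seed gives identical output.
#' @return Data frame `plot_id, stage, treatment, variety, lai,
#'   vis_factor, nir_factor, soil_factor`.
#' @export
sample_lai <- function(layout, params, seed = 1L) {
  stopifnot(inherits(layout, "field_layout"),
            inherits(params, "canopy_scene_params"))
  n <- layout$n_plots
  treat <- .assign_treatments(n)
  vari <- .assign_varieties(n)
  st <- lai_stages()
  with_seed(seed, {
    recs <- lapply(seq_along(st), function(si) {
      mu <- params$stage_lai_mean[[si]] *
        unname(params$treatment_factor[treat])
      data.frame(plot_id = seq_len(n), stage = st[si], treatment = treat,
                 variety = vari,
                 lai = .rtruncnorm0(n, mu, params$stage_lai_sd[si]),
                 vis_factor = exp(rnorm(n, 0, params$leaf_vis_sd)),
                 nir_factor = exp(rnorm(n, 0, params$leaf_nir_sd)),
                 soil_factor = exp(rnorm(n, 0, params$soil_sd)))
    })
    do.call(rbind, recs)
  })
}

# Per-plot column of local LAI across the row direction (raised cosine).
.local_lai_profile <- function(lai, y_rel_cm, params) {
  lai * (1 + params$mod_depth *
           cos(2 * pi * y_rel_cm / params$row_spacing_cm))
}

#' Render one field scene
#'
#' Local canopy cover follows the plot's LAI modulated by a raised-cosine
#' row profile across the row direction; each pixel mixes soil and leaf
#' reflectance through the Beer-law gap fraction `P = exp(-k * LAI_local)`
#' as `P * soil + (1 - P) * leaf`. Separator strips render as dark film.
#' Gaussian noise (sd `noise_sd`) is added and values clipped to \[0, 1\];
#' the RGB sensor is then scaled to digital numbers 0-255.
#'
#' @param layout A [build_layout] result.
#' @param truth Ground-truth table from [sample_lai].
#' @param params A [scene_params] object.
#' @param sensor `"rgb"` (1 cm native DN) or `"mca"` (8 cm native
#'   reflectance).
#' @param stage One of [lai_stages()].
#' @param seed Integer seed for the noise stream.
#' @return A [lai_raster].
#' @export
render_scene <- function(layout, truth, params, sensor = c("mca", "rgb"),
                         stage = "jointing", seed = 1L) {
  sensor <- match.arg(sensor)
  stopifnot(inherits(layout, "field_layout"),
            inherits(params, "canopy_scene_params"))
  if (!stage %in% lai_stages()) stop("unknown stage: ", stage)
  sp <- params$spectra[[sensor]]
  if (is.null(sp)) stop("no spectra configured for sensor ", sensor)
  res <- params$base_res_cm[[sensor]]
  nr <- as.integer(floor(layout$scene_rows_cm / res))
  nc <- as.integer(floor(layout$scene_cols_cm / res))
  nb <- length(sp$bands)
  rois <- layout_rois(layout, res)
  tr <- truth[truth$stage == stage, ]
  lai_of <- tr$lai[match(rois$plot_id, tr$plot_id)]
  if (anyNA(lai_of)) stop("ground truth missing for stage ", stage)
  # per-plot spectral factors (1 when the truth table carries none)
  fac <- function(col) if (col %in% names(tr))
    tr[[col]][match(rois$plot_id, tr$plot_id)] else rep(1, nrow(rois))
  vis_f <- fac("vis_factor") * params$stage_leaf_vis[[stage]]
  nir_f <- fac("nir_factor") * params$stage_leaf_nir[[stage]]
  soil_f <- fac("soil_factor")
  band_wl <- suppressWarnings(as.numeric(sp$bands))
  is_nir <- !is.na(band_wl) & band_wl >= 750
  # one gap-fraction column profile per plot (stripes vary across rows)
  gap <- lapply(seq_len(nrow(rois)), function(p) {
    y_rel <- (seq_len(rois$n_rows[p]) - 0.5) * res
    exp(-params$k * .local_lai_profile(lai_of[p], y_rel, params))
  })
  bands <- with_seed(seed, lapply(seq_len(nb), function(b) {
    x <- matrix(params$film_reflectance, nr, nc)
    for (p in seq_len(nrow(rois))) {
      r0 <- rois$row0[p]; c0 <- rois$col0[p]
      leaf_b <- min(1, sp$leaf[b] *
                      (if (is_nir[b]) nir_f[p] else vis_f[p]))
      soil_b <- min(1, sp$soil[b] * soil_f[p])
      x[(r0 + 1L):(r0 + rois$n_rows[p]),
        (c0 + 1L):(c0 + rois$n_cols[p])] <-
        gap[[p]] * soil_b + (1 - gap[[p]]) * leaf_b
    }
    if (params$noise_sd > 0)
      x <- x + rnorm(nr * nc, 0, params$noise_sd)
    x[x < 0] <- 0
    x[x > 1] <- 1
    if (sensor == "rgb") x <- round(x * 255)
    x
  }))
  v <- array(unlist(bands, use.names = FALSE), c(nr, nc, nb))
  lai_raster(v, sp$bands, res,
             kind = if (sensor == "rgb") "dn" else "reflectance")
}

#' Generate the full synthetic dataset
#'
#' Renders one raster per stage and sensor over a common layout and
#' ground-truth draw; optionally writes everything (rasters, ground-truth
#' CSV, per-sensor plot ROI CSVs) to a directory. All randomness derives
#' deterministically from `seed`.
#'
#' @param layout A [build_layout] result.
#' @param params A [scene_params] object.
#' @param seed Master integer seed.
#' @param sensors Which sensors to render.
#' @param stages Which stages to render.
#' @param out_dir Optional output directory (created if missing).
#' @return List with `truth`, `rois` (per sensor), `rasters` (nested
#'   `rasters[[stage]][[sensor]]`), `layout`, `params`, and `files` when
#'   written.
#' @export
generate_dataset <- function(layout = build_layout(),
                             params = scene_params(), seed = 1L,
                             sensors = c("rgb", "mca"),
                             stages = lai_stages(), out_dir = NULL) {
  truth <- sample_lai(layout, params, seed = derive_seed(seed, 1))
  rois <- lapply(stats::setNames(sensors, sensors), function(s) {
    r <- layout_rois(layout, params$base_res_cm[[s]])
    r$treatment <- .assign_treatments(layout$n_plots)
    r$variety <- .assign_varieties(layout$n_plots)
    r
  })
  rasters <- lapply(stats::setNames(stages, stages), function(st) {
    lapply(stats::setNames(sensors, sensors), function(s)
      render_scene(layout, truth, params, sensor = s, stage = st,
                   seed = derive_seed(seed, 2, match(st, lai_stages()),
                                      match(s, c("rgb", "mca")))))
  })
  out <- list(truth = truth, rois = rois, rasters = rasters,
              layout = layout, params = params, seed = seed)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    files <- character(0)
    f <- file.path(out_dir, "ground_truth.csv")
    utils::write.csv(truth, f, row.names = FALSE)
    files <- c(files, f)
    for (s in sensors) {
      f <- file.path(out_dir, paste0("rois_", s, ".csv"))
      utils::write.csv(rois[[s]], f, row.names = FALSE)
      files <- c(files, f)
    }
    for (st in stages) for (s in sensors) {
      f <- file.path(out_dir, sprintf("scene_%s_%s.tif", st, s))
      write_raster(rasters[[st]][[s]], f)
      files <- c(files, f, .sidecar_path(f))
    }
    out$files <- files
  }
  out
}
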