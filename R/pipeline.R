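#' Configuration for a full pipeline run
#'
#' @param out_dir Run directory (created; all artifacts land beneath it).
#' @param seed Master seed driving every random stage.
#' @param layout,params Field layout and scene parameters.
#' @param sensors Sensors to simulate and analyse.
#' @param texture_bands Named band per sensor used for texture (defaults:
#'   RGB blue, multispectral 680 nm).
#' @param ladders Named list of resolution ladders per sensor.
#' @param glcm A [glcm_config].
#' @param algorithms Modeling algorithms for the comparison report.
#' @param map_texture_res_cm Texture resolution (cm) used for the
#'   pixel-wise LAI maps; the mapped model is refitted on the
#'   multispectral indices plus plot means of the sliding-window
#'   textures of this single scale (see [sliding_plot_features]), so the
#'   coefficients transfer to per-pixel prediction.
#' @return List of class `"lai_run_config"`.
#' @export
run_config <- function(out_dir, seed = 1L, layout = build_layout(),
                       params = scene_params(),
                       sensors = c("rgb", "mca"),
                       texture_bands = c(rgb = "B", mca = "680"),
                       ladders = list(rgb = resolution_ladder("rgb"),
                                      mca = resolution_ladder("mca")),
                       glcm = glcm_config(),
                       algorithms = c("msr", "rf"),
                       map_texture_res_cm = 48) {
  if (missing(out_dir) || !nzchar(out_dir))
    stop("config error: `out_dir` is required")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 layout = layout, params = params, sensors = sensors,
                 texture_bands = texture_bands, ladders = ladders,
                 glcm = glcm, algorithms = algorithms,
                 map_texture_res_cm = map_texture_res_cm),
            class = "lai_run_config")
}

.stage_ctx <- function(stage_name, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage_name, "' failed: ",
         conditionMessage(e), call. = FALSE))
  message(sprintf("[%s] done in %.1f s", stage_name,
                  proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full analysis pipeline
#'
#' generate -> resample -> extract spectral indices and multiscale
#' textures -> correlation screening -> model comparison -> per-stage LAI
#' maps, all under one seed, with a manifest listing every artifact and
#' its MD5 hash. Two runs with the same configuration and seed produce
#' identical manifests.
#'
#' @param config A [run_config].
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "lai_run_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  files <- character(0)
  add <- function(f) files <<- c(files, f)

  ds <- .stage_ctx("generate", generate_dataset(
    config$layout, config$params, seed = config$seed,
    sensors = config$sensors, out_dir = file.path(out, "scene")))
  add(ds$files)
  stages <- lai_stages()

  feats <- .stage_ctx("extract", {
    fl <- list()
    for (s in config$sensors) {
      ras <- lapply(stats::setNames(stages, stages),
                    function(st) ds$rasters[[st]][[s]])
      si <- plot_si_table(ras, ds$rois[[s]], sensor = s, truth = ds$truth)
      tex <- plot_texture_table(ras, config$texture_bands[[s]],
                                ds$rois[[s]],
                                scales = config$ladders[[s]],
                                config = config$glcm, truth = ds$truth)
      for (what in c("si", "tex")) {
        f <- file.path(out, sprintf("features_%s_%s.csv", what, s))
        utils::write.csv(if (what == "si") si else tex, f,
                         row.names = FALSE)
        add(f)
      }
      fl[[s]] <- list(si = si, tex = tex)
    }
    fl
  })

  .stage_ctx("screen", {
    for (s in config$sensors) {
      reps <- lapply(c(as.list(stages), list("multi")), function(sc)
        rbind(correlate(feats[[s]]$si, scope = sc),
              correlate(feats[[s]]$tex, scope = sc)))
      rep_all <- do.call(rbind, reps)
      f <- file.path(out, sprintf("correlations_%s.csv", s))
      utils::write.csv(rep_all, f, row.names = FALSE)
      add(f)
    }
  })

  models <- .stage_ctx("fit", {
    split <- split_2to1(ds$truth$plot_id, seed = derive_seed(config$seed, 9))
    reports <- list()
    for (s in config$sensors) {
      si_cols <- si_names(s)
      tex_cols <- setdiff(names(feats[[s]]$tex),
                          c("plot_id", "stage", "treatment", "variety",
                            "lai"))
      merged <- merge(feats[[s]]$si, feats[[s]]$tex[, c("plot_id", "stage",
                                                        tex_cols)],
                      by = c("plot_id", "stage"), sort = TRUE)
      sets <- list(si = si_cols, texture = tex_cols,
                   si_texture = c(si_cols, tex_cols))
      cmp <- compare_feature_sets(merged, sets, split = split,
                                  algorithms = config$algorithms,
                                  seed = derive_seed(config$seed, 17))
      cmp$metrics <- cbind(sensor = s, cmp$metrics)
      reports[[s]] <- list(cmp = cmp, merged = merged)
    }
    metrics <- do.call(rbind, lapply(reports, function(r) r$cmp$metrics))
    rownames(metrics) <- NULL
    f <- file.path(out, "model_report.csv")
    utils::write.csv(metrics, f, row.names = FALSE)
    add(f)
    eqs <- unlist(lapply(names(reports), function(s)
      lapply(reports[[s]]$cmp$equations, render_equation)),
      use.names = FALSE)
    f <- file.path(out, "equations.json")
    jsonlite::write_json(eqs, f, auto_unbox = FALSE)
    add(f)
    list(split = split, reports = reports)
  })

  .stage_ctx("map", {
    if (!"mca" %in% config$sensors) {
      message("no multispectral sensor configured; skipping maps")
    } else {
      # refit on plot means of the *sliding-window* textures at the map
      # scale, so the fitted coefficients see the same feature definition
      # (global quantization, centred window) as the pixel-wise predictor
      tex_rows <- do.call(rbind, lapply(stages, function(st) {
        f <- sliding_plot_features(ds$rasters[[st]][["mca"]],
                                   config$texture_bands[["mca"]],
                                   ds$rois[["mca"]],
                                   res_cm = config$map_texture_res_cm,
                                   config = config$glcm)
        cbind(stage = st, f)
      }))
      map_feats <- merge(feats[["mca"]]$si, tex_rows,
                         by = c("plot_id", "stage"), sort = TRUE)
      cali <- map_feats[map_feats$plot_id %in% models$split$cali, ]
      scale_cols <- unlist(lapply(
        c(as.list(glcm_stat_codes()), .ndt_pairs()),
        texture_feature_name, res_cm = config$map_texture_res_cm))
      map_model <- fit_msr(cali, c(si_names("mca"),
                                   intersect(scale_cols,
                                             names(map_feats))))
      f <- file.path(out, "map_equation.txt")
      writeLines(render_equation(map_model), f)
      add(f)
      for (st in stages) {
        map <- predict_map(map_model, mca = ds$rasters[[st]][["mca"]],
                           config = config$glcm,
                           texture_sensor = "mca",
                           texture_band = config$texture_bands[["mca"]])
        f <- file.path(out, sprintf("lai_map_%s.tif", st))
        write_raster(map, f)
        add(c(f, .sidecar_path(f)))
      }
    }
  })

  manifest <- .stage_ctx("manifest", {
    rel <- sort(unique(sub(paste0("^", normalizePath(out), "/?"), "",
                           normalizePath(files))))
    hashes <- unname(tools::md5sum(file.path(normalizePath(out), rel)))
    man <- list(seed = config$seed,
                n_plots = config$layout$n_plots,
                sensors = config$sensors,
                artifacts = data.frame(path = rel, md5 = hashes))
    jsonlite::write_json(man, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    man
  })
  invisible(manifest)
}
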