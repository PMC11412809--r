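test_that("quantization is linear min-max onto 0..levels-1", {
  m <- matrix(c(0, 51, 255, 128), 2, 2)
  q <- quantize(m, 32)
  expect_identical(q[1, 1], 0L)
  expect_identical(q[1, 2], 31L)          # the maximum maps to levels - 1
  expect_identical(q[2, 1], 6L)  # floor(51 / 255 * 32)
  expect_identical(quantize(matrix(7, 3, 3), 32),
                   matrix(0L, 3, 3))      # constant grid maps to level 0
  qna <- quantize(matrix(c(1, NA, 2, Inf), 2, 2), 4)
  expect_true(is.na(qna[2, 1]) && is.na(qna[2, 2]))
  expect_error(quantize(matrix(NA_real_, 2, 2), 4), "no finite")
  expect_error(quantize(m, 1), ">= 2")
})

test_that("the GLCM is a normalized, symmetric pair histogram", {
  q <- matrix(c(0L, 1L, 1L, 0L, 2L, 2L), 2, 3)
  cfg <- glcm_config(levels = 3)
  P <- glcm(q, cfg)
  expect_equal(sum(P), 1)
  expect_identical(P, t(P))             # symmetric counting
  # offset (1, 0): pairs (0,1), (1,0), (2,2) each counted both ways
  expect_equal(P[1, 2], 1 / 3)
  expect_equal(P[3, 3], 1 / 3)
  expect_error(glcm(matrix(0L, 1, 3), cfg), "too small for offset")
  expect_error(glcm_config(offset = c(0, 0)), "offset")
})

test_that("the checkerboard GLCM matches the closed form", {
  q <- (outer(1:8, 1:8, `+`)) %% 2L
  st <- haralick_stats(glcm(q, glcm_config(levels = 2)))
  expect_identical(unname(st["Mea"]), 0.5)
  expect_identical(unname(st["Var"]), 0.25)
  expect_identical(unname(st["Hom"]), 0.5)
  expect_identical(unname(st["Con"]), 1)
  expect_identical(unname(st["Dis"]), 1)
  expect_identical(unname(st["Ent"]), log(2))
  expect_identical(unname(st["Sec"]), 0.5)
  expect_identical(unname(st["Cor"]), -1)
})

test_that("haralick_stats validates input and handles degeneracy", {
  expect_error(haralick_stats(matrix(1, 2, 2)), "normalized")
  # constant window: single-cell GLCM, zero marginal variance, Cor = 1
  st <- haralick_stats(glcm(matrix(0L, 4, 4), glcm_config(levels = 4)))
  expect_equal(unname(st["Cor"]), 1)
  expect_equal(unname(st["Hom"]), 1)
  expect_equal(unname(st["Con"]), 0)
})

test_that("glcm and haralick_stats agree with the naive reference", {
  for (i in 1:10) {
    q <- with_seed(100 + i,
                   matrix(sample(0:5, 48, replace = TRUE), 6, 8))
    cfg <- glcm_config(levels = 6)
    expect_equal(glcm(q, cfg), naive_glcm(q, 6), tolerance = 1e-12)
    expect_equal(haralick_stats(glcm(q, cfg)),
                 naive_haralick(naive_glcm(q, 6)), tolerance = 1e-12)
  }
  # asymmetric and column-offset variants
  q <- with_seed(7, matrix(sample(0:3, 30, replace = TRUE), 5, 6))
  cfg <- glcm_config(levels = 4, offset = c(0, 1), symmetric = FALSE,
                     angle_mode = "fixed")
  expect_equal(glcm(q, cfg), naive_glcm(q, 4, c(0L, 1L), FALSE),
               tolerance = 1e-12)
})

test_that("normalized-difference textures behave like NDVI", {
  expect_equal(ndt(3, 1), 0.5)
  expect_equal(ndt(1, 3), -0.5)
  expect_equal(ndt(c(3, 2), c(1, 2)), c(0.5, 0))
  expect_true(is.nan(ndt(1, -1)))
  expect_true(is.nan(ndt(0, 0)))
})

test_that("texture names render and parse consistently", {
  expect_identical(texture_feature_name("Hom", 40), "Hom40")
  expect_identical(texture_feature_name(c("Mea", "Cor"), 48), "meacor48")
  p <- parse_texture_name("meacor48")
  expect_identical(p$kind, "ndt")
  expect_identical(p$stats, c("Mea", "Cor"))
  expect_equal(p$res_cm, 48)
  p2 <- parse_texture_name("Hom40")
  expect_identical(p2$kind, "raw")
  expect_identical(p2$stats, "Hom")
  # single lowercase raw codes, as occasionally printed, canonicalize
  p3 <- parse_texture_name("cor40")
  expect_identical(p3$kind, "raw")
  expect_identical(p3$stats, "Cor")
  expect_null(parse_texture_name("NDVI"))
  expect_null(parse_texture_name("meaxyz8"))
  # round trip over every raw code and pair
  for (s in glcm_stat_codes())
    expect_identical(parse_texture_name(texture_feature_name(s, 8))$stats,
                     s)
})

test_that("plot_texture_table is wide with 36 features per scale", {
  lay <- tiny_layout(6)
  par <- scene_params()
  ds <- generate_dataset(lay, par, seed = 3, sensors = "mca")
  ras <- lapply(ds$rasters, `[[`, "mca")
  tab <- plot_texture_table(ras, "680", ds$rois$mca, scales = c(8, 16),
                            truth = ds$truth)
  expect_equal(nrow(tab), 6 * 3)
  id_cols <- c("plot_id", "stage", "lai", "treatment", "variety")
  expect_equal(ncol(tab), length(id_cols) + 2 * 36)
  expect_true(all(c("Mea8", "Cor16", "meacor8", "entsec16") %in%
                    names(tab)))

  # spot-check one raw statistic against a direct computation
  one <- select_bands(ras$jointing, "680")
  roi16 <- roi_at_scale(ds$rois$mca[2, ], 8, 16, shrink = 1L)
  sub <- crop_plot(resample_nearest(one, 16), roi16)
  st <- haralick_stats(glcm(quantize(sub$values[, , 1], 32)))
  row <- tab[tab$stage == "jointing" &
               tab$plot_id == ds$rois$mca$plot_id[2], ]
  expect_equal(row$Mea16, unname(st["Mea"]))
  expect_equal(row$meacor16, ndt(st[["Mea"]], st[["Cor"]]))
})

test_that("plots too small for a scale are NA-filled with a warning", {
  lay <- build_layout(4, plot_w_m = 0.5, plot_h_m = 0.5, buffer_cm = 16)
  par <- scene_params()
  tr <- sample_lai(lay, par, seed = 1)
  ras <- list(booting = render_scene(lay, tr, par, "mca", "booting"))
  rois <- layout_rois(lay, 8)
  expect_warning(tab <- plot_texture_table(ras, "680", rois,
                                           scales = c(8, 48),
                                           truth = NULL),
                 "too small")
  expect_true(all(is.na(tab$Mea48)))
  expect_true(all(is.finite(tab$Mea8)))
})

test_that("sliding textures preserve shape and handle flat regions", {
  r <- random_mca_raster(20, 16, seed = 6)
  st <- sliding_texture(r, "680", glcm_config(levels = 8, window = 5),
                        stats = c("Mea", "Hom", "Cor"))
  expect_identical(names(st), c("Mea", "Hom", "Cor"))
  expect_equal(dim(st$Mea), c(20L, 16L))
  expect_true(all(is.finite(st$Hom)))

  flat <- lai_raster(matrix(0.5, 12, 12), "680", 8, kind = "reflectance")
  sf <- sliding_texture(flat, "680", glcm_config(levels = 8, window = 5))
  expect_true(all(sf$Hom == 1))
  expect_true(all(sf$Con == 0))
  expect_true(all(sf$Cor == 1))

  expect_error(sliding_texture(r, "680", glcm_config(window = 1)),
               "window must exceed")
  expect_error(sliding_texture(r, "680", glcm_config(window = 21)),
               "larger than the raster")
})

test_that("sliding texture centre windows match whole-window GLCM stats", {
  r <- random_mca_raster(15, 15, seed = 8)
  cfg <- glcm_config(levels = 8, window = 5)
  st <- sliding_texture(r, "680", cfg, stats = "Mea")
  # away from edges the window is fully interior: compare to a direct GLCM
  q <- quantize(get_band(r, "680"), 8)   # global quantization
  sub <- q[6:10, 6:10]
  want <- haralick_stats(glcm(sub, cfg))[["Mea"]]
  expect_equal(st$Mea[8, 8], want)
})

test_that("sliding plot features average map-scale textures per plot", {
  lay <- tiny_layout(6)
  ds <- generate_dataset(lay, scene_params(), seed = 4, sensors = "mca")
  ras <- ds$rasters$booting$mca
  spf <- sliding_plot_features(ras, "680", ds$rois$mca, res_cm = 16)
  expect_equal(nrow(spf), 6L)
  expect_equal(ncol(spf), 1L + 36L)
  expect_true(all(c("plot_id", "Mea16", "Cor16", "meacor16",
                    "entsec16") %in% names(spf)))
  expect_true(all(is.finite(as.matrix(spf[, -1L]))))

  # cross-check one plot against a direct sliding-texture average
  st <- sliding_texture(resample_nearest(select_bands(ras, "680"), 16),
                        "680", glcm_config(), stats = "Mea")
  roi <- roi_at_scale(ds$rois$mca[3, ], 8, 16, shrink = 1L)
  rr <- (roi$row0 + 1L):(roi$row0 + roi$n_rows)
  cc <- (roi$col0 + 1L):(roi$col0 + roi$n_cols)
  expect_equal(spf$Mea16[3], mean(st$Mea[rr, cc]))
  expect_equal(spf$meacor16[3], ndt(spf$Mea16[3], spf$Cor16[3]))
})

test_that("sliding plot features: flat raster and vanishing windows", {
  flat <- lai_raster(matrix(0.4, 64, 64), "680", 8, kind = "reflectance")
  rois <- data.frame(plot_id = c("P01", "P02"),
                     row0 = c(2L, 12L), col0 = c(2L, 12L),
                     n_rows = c(10L, 2L), n_cols = c(10L, 2L))
  spf <- sliding_plot_features(flat, "680", rois, res_cm = 8)
  expect_equal(spf$Hom8[1], 1)
  expect_equal(spf$Con8[1], 0)
  expect_equal(spf$Cor8[1], 1)

  # at 48 cm the 2x2-pixel plot shrinks to nothing -> NA row
  spf48 <- sliding_plot_features(flat, "680", rois, res_cm = 48)
  expect_true(is.na(spf48$Mea48[2]))
})
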