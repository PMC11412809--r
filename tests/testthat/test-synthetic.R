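test_that("with_seed is reproducible and leaves the RNG state alone", {
  set.seed(42)
  before <- .Random.seed
  a <- with_seed(7, runif(5))
  expect_identical(.Random.seed, before)
  b <- with_seed(7, runif(5))
  expect_identical(a, b)
  expect_false(identical(a, with_seed(8, runif(5))))
})

test_that("derive_seed is deterministic and stays below 2^31", {
  s1 <- derive_seed(1, 2, 3)
  expect_identical(s1, derive_seed(1, 2, 3))
  expect_false(s1 == derive_seed(1, 3, 2))
  expect_true(s1 >= 0 && s1 < 2^31)
  many <- vapply(1:500, function(i) derive_seed(123, i), integer(1))
  expect_true(all(many >= 0 & many < 2^31))
})

test_that("scene parameters are validated", {
  expect_error(scene_params(k = 0), "positive")
  expect_error(scene_params(mod_depth = 1), "mod_depth")
  expect_error(scene_params(stage_lai_mean = c(jointing = 3, booting = 2,
                                               heading = 5)),
               "must increase")
  expect_error(scene_params(stage_lai_mean = c(a = 1)), "needs entries")
  expect_error(scene_params(leaf_vis_sd = -1), ">= 0")
  expect_error(scene_params(stage_leaf_vis = c(jointing = 1)),
               "stage leaf factors")
  p <- scene_params()
  expect_s3_class(p, "canopy_scene_params")
  expect_identical(names(p$stage_lai_mean), lai_stages())
})

test_that("the default layout is a 12 x 6 grid of 4 x 8 m plots", {
  lay <- build_layout()
  expect_identical(lay$n_plots, 72L)
  expect_identical(unname(lay$grid), c(12L, 6L))
  expect_equal(lay$scene_rows_cm, 12 * 400 + 13 * 48)
  expect_equal(lay$scene_cols_cm, 6 * 800 + 7 * 48)
  expect_equal(nrow(lay$origins), 72L)
  expect_equal(lay$origins$row0_cm[1], 48)
  expect_equal(lay$origins$col0_cm[1], 48)

  rois <- layout_rois(lay, 8)
  expect_equal(rois$n_rows[1], 50L)
  expect_equal(rois$n_cols[1], 100L)
  expect_equal(rois$row0[1], 6L)
})

test_that("ground truth draws follow the stage and treatment design", {
  lay <- tiny_layout(12)
  par0 <- scene_params(stage_lai_sd = 0)
  tr <- sample_lai(lay, par0, seed = 5)
  expect_equal(nrow(tr), 12 * 3)
  expect_identical(sort(unique(tr$stage)), sort(lai_stages()))
  # with zero spread each plot sits exactly at its treatment-scaled mean
  expect_equal(tr$lai,
               par0$stage_lai_mean[tr$stage] *
                 unname(par0$treatment_factor[tr$treatment]),
               ignore_attr = TRUE)

  par1 <- scene_params()
  t1 <- sample_lai(lay, par1, seed = 5)
  expect_identical(t1, sample_lai(lay, par1, seed = 5))
  expect_false(identical(t1$lai, sample_lai(lay, par1, seed = 6)$lai))
  expect_true(all(t1$lai >= 0))
  expect_true(all(c("vis_factor", "nir_factor", "soil_factor") %in%
                    names(t1)))
})

test_that("rendered scenes have the right shape, background and kinds", {
  lay <- tiny_layout(6)
  par0 <- scene_params(noise_sd = 0, leaf_vis_sd = 0, leaf_nir_sd = 0,
                       soil_sd = 0)
  tr <- sample_lai(lay, par0, seed = 1)

  mca <- render_scene(lay, tr, par0, sensor = "mca", stage = "booting")
  expect_identical(mca$kind, "reflectance")
  expect_equal(mca$res_cm, 8)
  expect_equal(dim(mca)[3], 12L)
  expect_equal(dim(mca)[1], floor(lay$scene_rows_cm / 8))
  # corner pixel lies on the film buffer
  expect_equal(mca$values[1, 1, 1], par0$film_reflectance)

  rgb <- render_scene(lay, tr, par0, sensor = "rgb", stage = "booting")
  expect_identical(rgb$kind, "dn")
  expect_true(all(rgb$values == round(rgb$values)))
  expect_true(all(rgb$values >= 0 & rgb$values <= 255))

  par1 <- scene_params()
  a <- render_scene(lay, tr, par1, sensor = "mca", stage = "booting",
                    seed = 3)
  expect_identical(a$values,
                   render_scene(lay, tr, par1, sensor = "mca",
                                stage = "booting", seed = 3)$values)
  expect_false(identical(a$values,
                         render_scene(lay, tr, par1, sensor = "mca",
                                      stage = "booting", seed = 4)$values))
  expect_error(render_scene(lay, tr, par1, stage = "harvest"),
               "unknown stage")
})

test_that("denser canopies darken the red band and brighten the NIR", {
  lay <- tiny_layout(6)
  par0 <- scene_params(noise_sd = 0, leaf_vis_sd = 0, leaf_nir_sd = 0,
                       soil_sd = 0)
  tr <- data.frame(plot_id = 1:6, stage = "booting", treatment = "T7",
                   variety = "FY4", lai = seq(0.5, 6, length.out = 6))
  ras <- render_scene(lay, tr, par0, sensor = "mca", stage = "booting")
  rois <- layout_rois(lay, 8)
  red <- vapply(seq_len(6), function(p)
    mean(get_band(crop_plot(ras, rois[p, ]), "670")), numeric(1))
  nir <- vapply(seq_len(6), function(p)
    mean(get_band(crop_plot(ras, rois[p, ]), "800")), numeric(1))
  expect_true(all(diff(red) < 0))
  expect_true(all(diff(nir) > 0))
})

test_that("generate_dataset is deterministic and writes its artifacts", {
  lay <- tiny_layout(6)
  par <- scene_params()
  out <- file.path(tempdir(), "ds")
  ds <- generate_dataset(lay, par, seed = 11, sensors = "mca",
                         out_dir = out)
  expect_true(all(file.exists(ds$files)))
  expect_true(file.exists(file.path(out, "ground_truth.csv")))
  expect_true(file.exists(file.path(out, "scene_heading_mca.tif")))
  back <- read_raster(file.path(out, "scene_booting_mca.tif"))
  expect_identical(back$values, ds$rasters$booting$mca$values)

  ds2 <- generate_dataset(lay, par, seed = 11, sensors = "mca")
  expect_identical(ds2$truth, ds$truth)
  expect_identical(ds2$rasters$jointing$mca$values,
                   ds$rasters$jointing$mca$values)
  unlink(out, recursive = TRUE)
})
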