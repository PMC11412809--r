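test_that("lai_equation objects validate, render and print", {
  eq <- lai_equation(2.2, c(-3.2, 18.68), c("meacor48", "R900"))
  expect_identical(render_equation(eq), "LAI=2.2-3.2*meacor48+18.68*R900")
  expect_output(print(eq), "LAI=2.2-3.2\\*meacor48\\+18.68\\*R900")
  expect_error(lai_equation(1, c(1, 2), "x"), "equal length")
  expect_error(lai_equation(NA_real_), "finite")
})

test_that("parse_equation accepts the printed notation", {
  eq <- parse_equation("LAI=2.2-3.2*meacor48+18.68*R900")
  expect_equal(eq$intercept, 2.2)
  expect_identical(eq$terms$feature, c("meacor48", "R900"))
  expect_equal(eq$terms$coefficient, c(-3.2, 18.68))

  # '*' optional, coefficient may abut the feature, whitespace ignored
  eq2 <- parse_equation("LAI = -3.2meacor48 + 18.68R900+2.2")
  expect_equal(eq2$intercept, 2.2)
  expect_equal(eq2$terms$coefficient, c(-3.2, 18.68))

  # bare numbers accumulate into the intercept; bare features get coef 1
  eq3 <- parse_equation("LAI=1+2-0.5+NDVI")
  expect_equal(eq3$intercept, 2.5)
  expect_equal(eq3$terms$coefficient, 1)
  expect_identical(eq3$terms$feature, "NDVI")

  expect_error(parse_equation("NDVI=1"), "must start with 'LAI='")
  expect_error(parse_equation("LAI="), "no terms")
  expect_error(parse_equation("LAI=1+2*XYZ"), "unknown feature token 'XYZ'")
  expect_error(parse_equation("LAI=3*R455"), "R455")
})

test_that("sensor context resolves ambiguous tokens", {
  # VARI resolves by sensor; auto mode infers rgb from DN bands
  eq_rgb <- parse_equation("LAI=1-0.042B-4.85VARI")
  expect_identical(eq_rgb$terms$feature, c("B", "VARI_rgb"))
  eq_mca <- parse_equation("LAI=1+18.68R900-4.85VARI")
  expect_identical(eq_mca$terms$feature, c("R900", "VARI_mca"))
  eq_forced <- parse_equation("LAI=1-4.85VARI", sensor = "rgb")
  expect_identical(eq_forced$terms$feature, "VARI_rgb")

  # lowercase raw texture codes canonicalize
  eq_tex <- parse_equation("LAI=4.148-30.288*meacor40 + 28.014*cor40")
  expect_identical(eq_tex$terms$feature, c("meacor40", "Cor40"))
})

test_that("render and parse are mutually stable", {
  texts <- c("LAI=2.2-3.2*meacor48+18.68*R900",
             "LAI=6.085-0.042B-5.82ExB",
             "LAI=-38.476 + 74.826*Hom40 + 0.621*Var4-29.84*seccor4",
             "LAI=-0.209 + 32.94*R900-24.29*R800")
  for (tx in texts) {
    eq <- parse_equation(tx)
    again <- parse_equation(render_equation(eq))
    expect_equal(again$intercept, eq$intercept)
    expect_identical(again$terms$feature, eq$terms$feature)
    expect_equal(again$terms$coefficient, eq$terms$coefficient)
  }
})

test_that("evaluate_equation applies the linear form to records", {
  eq <- parse_equation("LAI=2.2-3.2*meacor48+18.68*R900")
  rec <- data.frame(meacor48 = c(0, 1), R900 = c(0, 0.1))
  expect_equal(evaluate_equation(eq, rec),
               c(2.2, 2.2 - 3.2 + 1.868))
  expect_equal(evaluate_equation(eq, list(meacor48 = 0.5, R900 = 0.2)),
               2.2 - 1.6 + 3.736)
  expect_error(evaluate_equation(eq, data.frame(R900 = 1)),
               "missing feature 'meacor48'")
})

test_that("the shipped equation library parses and round-trips", {
  lib <- equation_library()
  expect_true(nrow(lib) >= 20)
  expect_true(all(c("id", "source", "sensor", "label", "equation") %in%
                    names(lib)))
  for (i in seq_len(nrow(lib))) {
    eq <- parse_equation(lib$equation[i], sensor = lib$sensor[i])
    expect_s3_class(eq, "lai_equation")
    again <- parse_equation(render_equation(eq), sensor = lib$sensor[i])
    expect_equal(again$intercept, eq$intercept, tolerance = 1e-12)
    expect_identical(again$terms$feature, eq$terms$feature)
    expect_equal(again$terms$coefficient, eq$terms$coefficient,
                 tolerance = 1e-12)
  }
})

test_that("predict_map evaluates spectral equations per pixel", {
  mca <- random_mca_raster(30, 24, seed = 12)
  eq <- parse_equation("LAI=1+2*R900")
  map <- predict_map(eq, mca = mca)
  expect_identical(map$bands, "LAI")
  expect_identical(map$kind, "value")
  expect_equal(map$res_cm, 8)
  expect_equal(get_band(map, 1L), 1 + 2 * get_band(mca, "900"))

  eqi <- parse_equation("LAI=0.5+3*NDVI")
  mapi <- predict_map(eqi, mca = mca)
  expect_equal(get_band(mapi, 1L),
               0.5 + 3 * get_band(si_raster(mca, "NDVI"), 1L))
  expect_error(predict_map(eq), "at least one")
  expect_error(predict_map(parse_equation("LAI=1+0.1*G"), mca = mca),
               "RGB raster")
})

test_that("texture terms set the map resolution to the coarsest scale", {
  mca <- random_mca_raster(128, 128, seed = 13)
  eq <- parse_equation("LAI=1-2*meahom16+0.5*R900")
  map <- predict_map(eq, mca = mca)
  expect_equal(map$res_cm, 16)
  expect_equal(dim(map)[1:2], c(64L, 64L))
  expect_true(any(is.finite(map$values)))

  # hand-build the same map: sliding textures on the coarsened band plus
  # the NN-aligned R900 raster
  coarse <- resample_nearest(select_bands(mca, "680"), 16)
  st <- sliding_texture(coarse, "680", glcm_config(),
                        stats = c("Mea", "Hom"))
  r900 <- get_band(resample_nearest(select_bands(mca, "900"), 16), 1L)
  want <- 1 - 2 * ndt(st$Mea, st$Hom) + 0.5 * r900
  want[!is.finite(want)] <- NA
  expect_equal(get_band(map, 1L), want)

  expect_error(predict_map(parse_equation("LAI=1+Hom4"), mca = mca),
               "finer than")
})
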