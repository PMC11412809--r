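#' Linear LAI equation
#'
#' An intercept plus coefficient-times-feature terms, the printable form
#' of a stepwise regression model (`LAI = a + b1*f1 + b2*f2 + ...`).
#'
#' @param intercept Intercept in LAI units.
#' @param coefficients Numeric term coefficients.
#' @param features Feature names, one per coefficient, in the grammar
#'   accepted by [parse_equation].
#' @return Object of class `"lai_equation"`.
#' @export
lai_equation <- function(intercept, coefficients = numeric(0),
                         features = character(0)) {
  if (length(coefficients) != length(features))
    stop("coefficients and features must have equal length")
  if (!all(is.finite(c(intercept, coefficients))))
    stop("equation coefficients must be finite")
  structure(list(intercept = as.numeric(intercept),
                 terms = data.frame(coefficient = as.numeric(coefficients),
                                    feature = as.character(features),
                                    stringsAsFactors = FALSE)),
            class = "lai_equation")
}

.fmt_num <- function(x)
  format(x, digits = 15, scientific = FALSE, trim = TRUE)

#' Render an equation in the printable notation
#'
#' @param model A [lai_equation].
#' @return String of the form `"LAI=2.2-3.2*meacor48+18.68*R900"`.
#' @export
render_equation <- function(model) {
  stopifnot(inherits(model, "lai_equation"))
  out <- paste0("LAI=", .fmt_num(model$intercept))
  for (i in seq_len(nrow(model$terms))) {
    cf <- model$terms$coefficient[i]
    out <- paste0(out, if (cf >= 0) "+" else "-", .fmt_num(abs(cf)), "*",
                  model$terms$feature[i])
  }
  out
}

#' @export
print.lai_equation <- function(x, ...) {
  cat(render_equation(x), "\n")
  invisible(x)
}

.rgb_index_names <- c("ExR", "ExG", "ExB", "ExG_ExR", "VARI_rgb", "GRVI")
.mca_index_names <- c("NDVI", "NDRE", "EVI2", "GNDVI", "CI_rededge",
                      "CI_green", "VARI_mca", "OSAVI")

# Classify one feature token. Returns list(type, name, res_cm, stats).
.classify_feature <- function(tok, sensor = "auto") {
  if (tok %in% c("R", "G", "B"))
    return(list(type = "band_dn", name = tok))
  if (tok %in% c("r", "g", "b"))
    return(list(type = "si", name = tok, sensor = "rgb"))
  if (grepl("^R[0-9]+$", tok)) {
    wl <- as.numeric(sub("^R", "", tok))
    if (!wl %in% .mca_wavelengths)
      stop("unknown feature token '", tok,
           "': no such multispectral band")
    return(list(type = "band_refl", name = tok, wavelength = wl))
  }
  if (tok == "VARI") {
    nm <- if (identical(sensor, "rgb")) "VARI_rgb" else "VARI_mca"
    return(list(type = "si", name = nm,
                sensor = if (identical(sensor, "rgb")) "rgb" else "mca"))
  }
  if (tok %in% .rgb_index_names)
    return(list(type = "si", name = tok, sensor = "rgb"))
  if (tok %in% .mca_index_names)
    return(list(type = "si", name = tok, sensor = "mca"))
  tx <- parse_texture_name(tok)
  if (!is.null(tx))
    return(list(type = paste0("texture_", tx$kind),
                name = texture_feature_name(tx$stats, tx$res_cm),
                stats = tx$stats, res_cm = tx$res_cm))
  stop("unknown feature token '", tok, "'")
}

#' Parse a printed LAI equation
#'
#' Accepts the notation of the printed model tables: `"LAI="` followed by
#' signed terms, `*` optional between coefficient and feature, whitespace
#' ignored. Feature tokens may be digital-number bands (`R`, `G`, `B`),
#' chromatic coordinates, multispectral band reflectances (`R900`),
#' registered index names (`VARI` resolves per `sensor`), raw texture
#' statistics (`Hom40`, also tolerated lowercase as printed), and
#' normalized-difference textures (`meacor48`). Bare numbers accumulate
#' into the intercept.
#'
#' @param text Equation string.
#' @param sensor `"auto"`, `"rgb"` or `"mca"`; disambiguates `VARI`.
#'   `"auto"` picks `"rgb"` when the equation uses DN bands or RGB
#'   indices, else `"mca"`.
#' @return A [lai_equation]; unknown tokens raise an error naming them.
#' @export
parse_equation <- function(text, sensor = c("auto", "rgb", "mca")) {
  sensor <- match.arg(sensor)
  s <- gsub("[[:space:]]+", "", text)
  if (!grepl("^LAI=", s)) stop("equation must start with 'LAI='")
  s <- sub("^LAI=", "", s)
  if (nchar(s) == 0L) stop("equation has no terms")
  term_re <- paste0("^([+-]?)",
                    "((?:[0-9]+\\.?[0-9]*|\\.[0-9]+)(?:[eE][+-]?[0-9]+)?)?",
                    "\\*?",
                    "([A-Za-z][A-Za-z0-9_]*)?")
  raw_terms <- list()
  while (nchar(s) > 0L) {
    m <- regmatches(s, regexec(term_re, s))[[1]]
    if (length(m) == 0L || nchar(m[1]) == 0L)
      stop("cannot parse equation near '", s, "'")
    sign <- if (m[2] == "-") -1 else 1
    num <- m[3]; tok <- m[4]
    if (num == "" && tok == "")
      stop("cannot parse equation near '", s, "'")
    raw_terms[[length(raw_terms) + 1L]] <-
      list(coef = sign * (if (num == "") 1 else as.numeric(num)),
           token = tok)
    s <- substr(s, nchar(m[1]) + 1L, nchar(s))
  }
  toks <- vapply(raw_terms, `[[`, character(1), "token")
  if (sensor == "auto") {
    probe <- toks[toks != "" & toks != "VARI"]
    cls <- lapply(probe, .classify_feature, sensor = "auto")
    rgbish <- any(vapply(cls, function(cl)
      identical(cl$type, "band_dn") ||
        identical(cl$sensor, "rgb"), logical(1)))
    sensor <- if (rgbish) "rgb" else "mca"
  }
  intercept <- 0
  coefs <- numeric(0); feats <- character(0)
  for (tm in raw_terms) {
    if (tm$token == "") {
      intercept <- intercept + tm$coef
    } else {
      cl <- .classify_feature(tm$token, sensor = sensor)
      coefs <- c(coefs, tm$coef)
      feats <- c(feats, cl$name)
    }
  }
  lai_equation(intercept, coefs, feats)
}

#' Evaluate an equation on feature records
#'
#' @param model A [lai_equation].
#' @param record Named list or data frame supplying every term feature
#'   (one value or column each); a missing feature raises an error naming
#'   it.
#' @return Predicted LAI, one value per record row.
#' @export
evaluate_equation <- function(model, record) {
  stopifnot(inherits(model, "lai_equation"))
  out <- model$intercept
  for (i in seq_len(nrow(model$terms))) {
    f <- model$terms$feature[i]
    v <- record[[f]]
    if (is.null(v)) stop("record is missing feature '", f, "'")
    out <- out + model$terms$coefficient[i] * v
  }
  if (length(out) == 1L && is.data.frame(record) && nrow(record) > 1L)
    out <- rep(out, nrow(record))
  out
}

#' The shipped library of printed LAI equations
#'
#' All model equations of the multiscale-texture and feature-fusion
#' tables, as shipped in `extdata/equations.json`.
#'
#' @return Data frame `id, source, sensor, label, equation`.
#' @export
equation_library <- function() {
  path <- system.file("extdata", "equations.json", package = "canopylai",
                      mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# Feature raster for one equation term at its own resolution, as a plain
# matrix plus that resolution.
.term_feature_raster <- function(cl, rgb, mca, config, texture_sensor,
                                 texture_band) {
  need <- function(x, what) {
    if (is.null(x)) stop("resolution error: term needs the ", what,
                         " raster, which was not supplied")
    x
  }
  if (cl$type == "band_dn") {
    r <- need(rgb, "RGB")
    return(list(m = get_band(r, cl$name), res = r$res_cm))
  }
  if (cl$type == "band_refl") {
    r <- need(mca, "multispectral")
    return(list(m = get_band(r, as.character(cl$wavelength)),
                res = r$res_cm))
  }
  if (cl$type == "si") {
    r <- if (cl$sensor == "rgb") need(rgb, "RGB") else
      need(mca, "multispectral")
    return(list(m = compute_index(cl$name, r), res = r$res_cm))
  }
  ## texture term
  src <- if (texture_sensor == "rgb") need(rgb, "RGB") else
    need(mca, "multispectral")
  if (cl$res_cm < src$res_cm)
    stop("resolution error: texture at ", cl$res_cm,
         " cm finer than the ", texture_sensor, " native ", src$res_cm,
         " cm")
  one <- select_bands(src, texture_band)
  coarse <- resample_nearest(one, cl$res_cm)
  st <- sliding_texture(coarse, texture_band, config, stats = cl$stats)
  m <- if (cl$type == "texture_raw") st[[cl$stats[1L]]] else
    ndt(st[[cl$stats[1L]]], st[[cl$stats[2L]]])
  list(m = m, res = cl$res_cm)
}

#' Pixel-wise LAI map from a linear equation
#'
#' Every term's feature raster is built at its own stated resolution
#' (spectral terms per pixel at native resolution; texture terms via
#' sliding-window GLCM on the nearest-neighbour-coarsened band), all
#' feature rasters are aligned to the coarsest required resolution by the
#' same nearest-neighbour rule, and the linear form is evaluated per
#' pixel. Pixels with any fill-valued feature become `NA` (no-data).
#'
#' @param model A [lai_equation].
#' @param rgb Optional RGB [lai_raster] (DN) at native resolution.
#' @param mca Optional multispectral [lai_raster] at native resolution.
#' @param config [glcm_config] for sliding textures.
#' @param texture_sensor,texture_band Which band feeds texture terms
#'   (default the multispectral 680 nm band; RGB blue when only RGB is
#'   given).
#' @return Single-band [lai_raster] `"LAI"` at the coarsest term
#'   resolution.
#' @export
predict_map <- function(model, rgb = NULL, mca = NULL,
                        config = glcm_config(),
                        texture_sensor = if (is.null(mca)) "rgb" else "mca",
                        texture_band = if (texture_sensor == "mca") "680"
                        else "B") {
  stopifnot(inherits(model, "lai_equation"))
  if (is.null(rgb) && is.null(mca))
    stop("at least one of `rgb`, `mca` must be supplied")
  cls <- lapply(model$terms$feature, .classify_feature,
                sensor = if (is.null(mca)) "rgb" else "mca")
  ## validate resolvability before any computation
  for (cl in cls) {
    if (cl$type == "band_dn" && is.null(rgb))
      stop("resolution error: '", cl$name, "' needs the RGB raster")
    if (cl$type %in% c("band_refl") && is.null(mca))
      stop("resolution error: '", cl$name,
           "' needs the multispectral raster")
    if (cl$type == "si" && cl$sensor == "rgb" && is.null(rgb))
      stop("resolution error: '", cl$name, "' needs the RGB raster")
    if (cl$type == "si" && cl$sensor == "mca" && is.null(mca))
      stop("resolution error: '", cl$name,
           "' needs the multispectral raster")
  }
  base_res <- if (!is.null(mca)) mca$res_cm else rgb$res_cm
  res_of <- vapply(cls, function(cl)
    if (!is.null(cl$res_cm)) cl$res_cm else NA_real_, numeric(1))
  out_res <- max(c(base_res, res_of), na.rm = TRUE)
  feats <- lapply(cls, .term_feature_raster, rgb = rgb, mca = mca,
                  config = config, texture_sensor = texture_sensor,
                  texture_band = texture_band)
  aligned <- lapply(feats, function(fr) {
    r <- lai_raster(fr$m, "f", fr$res, kind = "value")
    get_band(resample_nearest(r, out_res), 1L)
  })
  if (length(aligned) > 0L) {
    nr <- min(vapply(aligned, nrow, integer(1)))
    nc <- min(vapply(aligned, ncol, integer(1)))
    acc <- matrix(model$intercept, nr, nc)
    for (i in seq_along(aligned))
      acc <- acc + model$terms$coefficient[i] *
        aligned[[i]][seq_len(nr), seq_len(nc)]
  } else {
    ref <- if (!is.null(mca)) mca else rgb
    ref_out <- resample_nearest(select_bands(ref, ref$bands[1L]), out_res)
    acc <- matrix(model$intercept, nrow(ref_out$values),
                  ncol(ref_out$values))
  }
  acc[!is.finite(acc)] <- NA
  lai_raster(acc, "LAI", out_res, kind = "value")
}
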