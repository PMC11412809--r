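#' The eight GLCM statistic codes
#'
#' Canonical order: mean, variance, homogeneity, contrast, dissimilarity,
#' entropy, second moment, correlation. Normalized-difference texture
#' pairs are enumerated in this order.
#'
#' @return Character vector of the 3-letter codes.
#' @export
glcm_stat_codes <- function()
  c("Mea", "Var", "Hom", "Con", "Dis", "Ent", "Sec", "Cor")

#' GLCM configuration
#'
#' @param levels Gray quantization depth (>= 2).
#' @param offset Integer pixel displacement `(dr, dc)`; `NULL` derives it
#'   from `angle_mode`.
#' @param symmetric Count each pair in both orders.
#' @param angle_mode `"perpendicular_to_rows"` (crop rows run along image
#'   columns, so the perpendicular displacement is `(1, 0)`) or
#'   `"fixed"` (use `offset` as given).
#' @param window Odd window size (pixels) for sliding-window mode.
#' @return A list of class `"glcm_config"`.
#' @export
glcm_config <- function(levels = 32L, offset = NULL, symmetric = TRUE,
                        angle_mode = c("perpendicular_to_rows", "fixed"),
                        window = 9L) {
  angle_mode <- match.arg(angle_mode)
  if (levels < 2L) stop("levels must be >= 2")
  if (is.null(offset))
    offset <- if (angle_mode == "perpendicular_to_rows") c(1L, 0L) else
      c(0L, 1L)
  offset <- as.integer(offset)
  if (all(offset == 0L)) stop("offset must not be (0, 0)")
  if (window %% 2L != 1L) stop("sliding window size must be odd")
  structure(list(levels = as.integer(levels), offset = offset,
                 symmetric = isTRUE(symmetric), angle_mode = angle_mode,
                 window = as.integer(window)),
            class = "glcm_config")
}

#' Linear min-max gray quantization
#'
#' Finite values are binned linearly into `{0, ..., levels - 1}`; the
#' minimum maps to 0, the maximum to `levels - 1`, and a constant grid
#' maps entirely to level 0. Non-finite cells become `NA` and are skipped
#' during pair counting.
#'
#' @param band Numeric matrix.
#' @param levels Number of gray levels (>= 2).
#' @return Integer matrix of the same shape.
#' @export
quantize <- function(band, levels = 32L) {
  if (levels < 2L) stop("levels must be >= 2")
  fin <- is.finite(band)
  if (!any(fin)) stop("cannot quantize: no finite values")
  lo <- min(band[fin]); hi <- max(band[fin])
  q <- band
  q[!fin] <- NA
  if (hi == lo) {
    q[fin] <- 0
  } else {
    q[fin] <- floor((band[fin] - lo) / (hi - lo) * levels)
    q[fin][q[fin] == levels] <- levels - 1
  }
  mode(q) <- "integer"
  matrix(q, nrow = nrow(band))
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurring gray-level pairs at the configured displacement and
#' normalizes to probabilities. With `symmetric = TRUE` each pair is also
#' counted in the reversed order.
#'
#' @param q Integer matrix from [quantize] (values in
#'   `0 .. levels - 1`, `NA` allowed).
#' @param config A [glcm_config].
#' @return `levels x levels` probability matrix (entries sum to 1).
#' @export
glcm <- function(q, config = glcm_config()) {
  L <- config$levels
  dr <- config$offset[1L]; dc <- config$offset[2L]
  nr <- nrow(q); nc <- ncol(q)
  r_src <- seq_len(nr - abs(dr)) + max(0L, -dr)
  c_src <- seq_len(nc - abs(dc)) + max(0L, -dc)
  if (length(r_src) < 1L || length(c_src) < 1L)
    stop("grid too small for offset (", dr, ",", dc, ")")
  a <- q[r_src, c_src, drop = FALSE]
  b <- q[r_src + dr, c_src + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no valid gray-level pairs")
  code <- a[ok] * L + b[ok]
  counts <- tabulate(code + 1L, nbins = L * L)
  P <- matrix(counts, nrow = L, ncol = L, byrow = TRUE)
  if (config$symmetric) P <- P + t(P)
  P / sum(P)
}

# Shared statistic kernel on the flattened probability vector with 0-based
# row (i) and column (j) indices.
.haralick_kernel <- function(p, i, j) {
  mea <- sum(i * p)
  muy <- sum(j * p)
  varx <- sum((i - mea)^2 * p)
  vary <- sum((j - muy)^2 * p)
  d <- i - j
  pos <- p > 0
  cor <- if (varx <= 0 || vary <= 0) 1.0 else
    sum((i - mea) * (j - muy) * p) / sqrt(varx * vary)
  c(Mea = mea,
    Var = varx,
    Hom = sum(p / (1 + d^2)),
    Con = sum(d^2 * p),
    Dis = sum(abs(d) * p),
    Ent = -sum(p[pos] * log(p[pos])),
    Sec = sum(p^2),
    Cor = cor)
}

#' The eight Haralick statistics of a GLCM
#'
#' `Mea = sum(i P)`, `Var = sum((i - Mea)^2 P)`,
#' `Hom = sum(P / (1 + (i - j)^2))`, `Con = sum((i - j)^2 P)`,
#' `Dis = sum(|i - j| P)`, `Ent = -sum(P log P)` over positive entries,
#' `Sec = sum(P^2)`, and `Cor` the correlation of the row and column
#' margins. A degenerate GLCM (zero marginal variance, e.g. a constant
#' window) takes `Cor = 1` by convention.
#'
#' @param P Normalized GLCM (square matrix summing to 1).
#' @return Named numeric vector of the 8 statistics.
#' @export
haralick_stats <- function(P) {
  if (abs(sum(P) - 1) > 1e-8) stop("GLCM must be normalized")
  i <- as.vector(row(P)) - 1
  j <- as.vector(col(P)) - 1
  .haralick_kernel(as.vector(P), i, j)
}

#' Normalized difference of two texture statistics
#'
#' `(t1 - t2) / (t1 + t2)`, the texture analogue of NDVI; antisymmetric,
#' and bounded in \[-1, 1\] for nonnegative inputs. A vanishing sum yields
#' the `NaN` fill value.
#'
#' @param t1,t2 Finite statistic values (vectorised).
#' @param eps Magnitude below which the denominator counts as zero.
#' @return The normalized difference.
#' @export
ndt <- function(t1, t2, eps = 1e-12) {
  s <- t1 + t2
  out <- (t1 - t2) / s
  out[abs(s) < eps] <- NaN
  out
}

#' Texture feature names
#'
#' Raw statistics render as the capitalized code plus the resolution in cm
#' (`Hom40`, `Mea1`); normalized-difference textures as the two lowercase
#' codes concatenated plus the resolution (`meacor48`).
#'
#' @param stats One code (raw) or two codes (NDT) from
#'   [glcm_stat_codes()].
#' @param res_cm Resolution in cm.
#' @return The feature name string.
#' @export
texture_feature_name <- function(stats, res_cm) {
  res <- format(res_cm, trim = TRUE)
  if (length(stats) == 1L) paste0(stats, res) else
    paste0(tolower(stats[1L]), tolower(stats[2L]), res)
}

#' Parse a texture feature name
#'
#' @param name Feature name as rendered by [texture_feature_name]. A
#'   single lowercase code (as occasionally printed) is accepted and
#'   canonicalized to the raw capitalized form.
#' @return List with `kind` (`"raw"` or `"ndt"`), `stats` (one or two
#'   codes), `res_cm`; or `NULL` if `name` is not a texture feature name.
#' @export
parse_texture_name <- function(name) {
  codes <- glcm_stat_codes()
  alt <- paste(tolower(codes), collapse = "|")
  m <- regmatches(name, regexec(paste0("^(", alt, ")(", alt,
                                       ")([0-9]+)$"), name,
                                ignore.case = FALSE))[[1]]
  if (length(m) == 4L && grepl("^[a-z]", name)) {
    s1 <- codes[match(m[2], tolower(codes))]
    s2 <- codes[match(m[3], tolower(codes))]
    return(list(kind = "ndt", stats = c(s1, s2),
                res_cm = as.numeric(m[4])))
  }
  m <- regmatches(name, regexec(paste0("^(", paste(codes, collapse = "|"),
                                       "|", alt, ")([0-9]+)$"),
                                name))[[1]]
  if (length(m) == 3L) {
    s <- codes[match(tolower(m[2]), tolower(codes))]
    return(list(kind = "raw", stats = s, res_cm = as.numeric(m[3])))
  }
  NULL
}

# All 28 NDT code pairs in canonical order.
.ndt_pairs <- function() {
  codes <- glcm_stat_codes()
  out <- list()
  for (i in seq_len(7L)) for (j in (i + 1L):8L)
    out[[length(out) + 1L]] <- c(codes[i], codes[j])
  out
}

#' Per-plot multiscale texture table
#'
#' For every plot, stage and ladder resolution: one GLCM over the whole
#' (border-shrunken) plot window of the chosen band, its 8 statistics, and
#' all 28 normalized-difference combinations. Gray levels are stretched
#' per plot window (min-max). Columns follow the texture name grammar
#' (`Mea8`, `meacor48`, ...).
#'
#' @param rasters_by_stage Named list `stage -> lai_raster` at native
#'   resolution.
#' @param band Band label to analyse (e.g. `"680"` for the multispectral
#'   red band, `"B"` for RGB blue).
#' @param rois Native-resolution plot ROI table.
#' @param scales Resolutions (cm) to cover; each `>=` native.
#' @param config A [glcm_config].
#' @param truth Optional ground truth merged in (`plot_id, stage, lai`).
#' @param shrink Border shrink (coarse pixels) applied when coarsening.
#' @return Wide data frame: ids/labels then 36 columns per scale. Plots
#'   whose window cannot hold the offset at some scale get `NA` there,
#'   with a warning.
#' @export
plot_texture_table <- function(rasters_by_stage, band, rois,
                               scales = resolution_ladder("mca"),
                               config = glcm_config(), truth = NULL,
                               shrink = 1L) {
  pairs <- .ndt_pairs()
  codes <- glcm_stat_codes()
  recs <- list()
  dropped <- 0L
  for (st in names(rasters_by_stage)) {
    ras <- rasters_by_stage[[st]]
    if (!band %in% ras$bands)
      stop("band ", band, " absent from stage ", st, " raster")
    native <- ras$res_cm
    one <- select_bands(ras, band)
    ladder <- lapply(scales, function(s) resample_nearest(one, s))
    for (p in seq_len(nrow(rois))) {
      rec <- data.frame(plot_id = rois$plot_id[p], stage = st)
      for (lab in intersect(c("treatment", "variety"), names(rois)))
        rec[[lab]] <- rois[[lab]][p]
      for (k in seq_along(scales)) {
        sc <- scales[k]
        roi_k <- if (sc == native) as.list(rois[p, ]) else
          roi_at_scale(rois[p, ], native, sc, shrink = shrink)
        vals <- rep(NA_real_, 36L)
        ok <- FALSE
        if (!is.null(roi_k) &&
            roi_k$n_rows > abs(config$offset[1L]) &&
            roi_k$n_cols > abs(config$offset[2L])) {
          sub <- crop_plot(ladder[[k]], roi_k)
          q <- quantize(sub$values[, , 1L], config$levels)
          stt <- haralick_stats(glcm(q, config))
          nd <- vapply(pairs, function(pr) ndt(stt[pr[1L]], stt[pr[2L]]),
                       numeric(1))
          vals <- c(unname(stt), unname(nd))
          ok <- TRUE
        }
        if (!ok) dropped <- dropped + 1L
        nms <- c(vapply(codes, texture_feature_name, character(1),
                        res_cm = sc),
                 vapply(pairs, texture_feature_name, character(1),
                        res_cm = sc))
        rec[nms] <- as.list(vals)
      }
      recs[[length(recs) + 1L]] <- rec
    }
  }
  if (dropped > 0L)
    warning(dropped, " plot-scale window(s) too small for the offset; ",
            "filled with NA")
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  if (!is.null(truth))
    out <- merge(truth[, c("plot_id", "stage", "lai")], out,
                 by = c("plot_id", "stage"), sort = TRUE)
  out
}

#' Sliding-window texture rasters
#'
#' Computes the GLCM statistics of a centred odd window around every pixel
#' of one band. Gray levels are stretched once over the whole band
#' (global min-max), and edges are handled by nearest-valid replication so
#' the output has the input's shape.
#'
#' @param raster A [lai_raster].
#' @param band Band label.
#' @param config A [glcm_config]; `config$window` sets the window size.
#' @param stats Which statistics to return (default all 8).
#' @return Named list of matrices, one per requested statistic.
#' @export
sliding_texture <- function(raster, band, config = glcm_config(),
                            stats = glcm_stat_codes()) {
  stopifnot(inherits(raster, "lai_raster"))
  stats <- match.arg(stats, glcm_stat_codes(), several.ok = TRUE)
  m <- get_band(raster, band)
  w <- config$window
  dr <- config$offset[1L]; dc <- config$offset[2L]
  if (w <= max(abs(dr), abs(dc))) stop("window must exceed the offset span")
  if (w > min(dim(m))) stop("window larger than the raster")
  L <- config$levels
  q <- quantize(m, L)
  h <- (w - 1L) %/% 2L
  nr <- nrow(q); nc <- ncol(q)
  pad_r <- pmin(pmax(seq_len(nr + 2L * h) - h, 1L), nr)
  pad_c <- pmin(pmax(seq_len(nc + 2L * h) - h, 1L), nc)
  qp <- q[pad_r, pad_c, drop = FALSE]
  # pair codes over the padded grid
  pr <- seq_len(nrow(qp) - abs(dr)) + max(0L, -dr)
  pc <- seq_len(ncol(qp) - abs(dc)) + max(0L, -dc)
  a <- qp[pr, pc, drop = FALSE]
  b <- qp[pr + dr, pc + dc, drop = FALSE]
  code <- a * L + b  # NA where either side is NA
  iidx <- (seq_len(L * L) - 1L) %/% L
  jidx <- (seq_len(L * L) - 1L) %% L
  out <- lapply(stats, function(s) matrix(NA_real_, nr, nc))
  names(out) <- stats
  wr <- w - abs(dr); wc <- w - abs(dc)
  for (r in seq_len(nr)) {
    rows <- r:(r + wr - 1L)
    for (cl in seq_len(nc)) {
      cw <- code[rows, cl:(cl + wc - 1L)]
      cw <- cw[!is.na(cw)]
      if (length(cw) == 0L) next
      counts <- tabulate(cw + 1L, nbins = L * L)
      if (config$symmetric) {
        Pm <- matrix(counts, L, L, byrow = TRUE)
        Pm <- Pm + t(Pm)
        p <- as.vector(t(Pm))
      } else p <- counts
      p <- p / sum(p)
      st <- .haralick_kernel(p, iidx, jidx)
      for (s in stats) out[[s]][r, cl] <- st[[s]]
    }
  }
  out
}

#' Plot means of sliding-window texture features at one scale
#'
#' Computes the sliding-window GLCM statistic rasters of one band at a
#' target resolution, averages each raw statistic over every plot window,
#' and takes the normalized differences of the averages. Because these
#' features come from the same global quantization and window definition
#' as the texture terms of [predict_map], a model fitted on this table
#' transfers to pixel-wise mapping without a feature-scale mismatch
#' (plot-window textures from [plot_texture_table] are stretched per plot
#' and do not).
#'
#' @param raster Native-resolution [lai_raster].
#' @param band Band label to analyse.
#' @param rois Native-resolution plot ROI table.
#' @param res_cm Texture scale in cm (`>=` native).
#' @param config A [glcm_config].
#' @param shrink Border shrink (coarse pixels) applied when coarsening.
#' @return Data frame: `plot_id` plus the 36 texture features named by
#'   the texture grammar at `res_cm` (`Mea48`, `meacor48`, ...). Plots
#'   whose coarse window vanishes get `NA`.
#' @export
sliding_plot_features <- function(raster, band, rois, res_cm,
                                  config = glcm_config(), shrink = 1L) {
  stopifnot(inherits(raster, "lai_raster"))
  native <- raster$res_cm
  coarse <- resample_nearest(select_bands(raster, band), res_cm)
  stt <- sliding_texture(coarse, band, config)
  codes <- glcm_stat_codes()
  pairs <- .ndt_pairs()
  nms <- c(vapply(codes, texture_feature_name, character(1),
                  res_cm = res_cm),
           vapply(pairs, texture_feature_name, character(1),
                  res_cm = res_cm))
  d <- dim(coarse)
  recs <- lapply(seq_len(nrow(rois)), function(p) {
    roi_k <- if (res_cm == native) as.list(rois[p, ]) else
      roi_at_scale(rois[p, ], native, res_cm, shrink = shrink)
    vals <- rep(NA_real_, 36L)
    if (!is.null(roi_k)) {
      rr <- (roi_k$row0 + 1L):min(roi_k$row0 + roi_k$n_rows, d[1L])
      cc <- (roi_k$col0 + 1L):min(roi_k$col0 + roi_k$n_cols, d[2L])
      m <- vapply(codes, function(s) mean(stt[[s]][rr, cc]), numeric(1))
      nd <- vapply(pairs, function(pr) ndt(m[[pr[1L]]], m[[pr[2L]]]),
                   numeric(1))
      vals <- c(unname(m), unname(nd))
    }
    rec <- data.frame(plot_id = rois$plot_id[p])
    rec[nms] <- as.list(vals)
    rec
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
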