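#' Correlate features with LAI
#'
#' Pearson correlation of every feature column against measured LAI,
#' either within one growth stage (`scope = "jointing"` etc.) or pooling
#' all stages (`scope = "multi"`). Records with fill values are excluded
#' pairwise; a zero-variance feature reports the `NA` fill value with a
#' warning.
#'
#' @param features Feature table with columns `stage`, `lai` and numeric
#'   feature columns.
#' @param scope One stage name or `"multi"`.
#' @param feature_names Columns to correlate; default every numeric column
#'   except ids and `lai`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Data frame `feature, scope, r, n`.
#' @export
correlate <- function(features, scope = "multi", feature_names = NULL,
                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!"lai" %in% names(features)) stop("feature table has no `lai` column")
  sub <- if (identical(scope, "multi")) features else
    features[features$stage == scope, ]
  if (is.null(feature_names)) {
    skip <- c("plot_id", "stage", "treatment", "variety", "lai")
    feature_names <- setdiff(names(features)[vapply(features, is.numeric,
                                                    logical(1))], skip)
  }
  if (nrow(sub) < 3L) stop("need at least 3 records in scope ", scope)
  res <- lapply(feature_names, function(f) {
    x <- sub[[f]]; y <- sub$lai
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    r <- if (n < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning("correlation undefined for feature ", f, " in scope ",
              scope)
      NA_real_
    } else stats::cor(x[ok], y[ok], method = method)
    data.frame(feature = f, scope = scope, r = r, n = n)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Feature-by-scale correlation grid
#'
#' Correlations of the raw texture statistics (or NDT pairs) of one band
#' against LAI at every ladder resolution, as a rectangular grid suitable
#' for a heatmap.
#'
#' @param features Multiscale texture feature table
#'   (see [plot_texture_table]).
#' @param scales Resolutions (cm) to include.
#' @param stats Statistic codes (raw, e.g. `glcm_stat_codes()`) or NDT
#'   pairs (list of 2-vectors).
#' @param scope Stage name or `"multi"`.
#' @return Matrix `stats x scales` of Pearson r (missing scales dropped
#'   with a warning).
#' @export
correlation_matrix <- function(features, scales, stats = glcm_stat_codes(),
                               scope = "multi") {
  if (!is.list(stats)) stats <- as.list(stats)
  keep <- logical(length(scales))
  cols <- matrix(NA_real_, nrow = length(stats), ncol = length(scales))
  row_lab <- vapply(stats, function(s)
    if (length(s) == 1L) s else paste0(s[1L], s[2L]), character(1))
  for (k in seq_along(scales)) {
    nms <- vapply(stats, texture_feature_name, character(1),
                  res_cm = scales[k])
    if (!all(nms %in% names(features))) {
      warning("scale ", scales[k], " cm absent from feature table; dropped")
      next
    }
    keep[k] <- TRUE
    rep_k <- correlate(features, scope = scope, feature_names = nms)
    cols[, k] <- rep_k$r[match(nms, rep_k$feature)]
  }
  out <- cols[, keep, drop = FALSE]
  dimnames(out) <- list(row_lab, as.character(scales[keep]))
  out
}
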