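#' Split plots 2:1 into calibration and validation sets
#'
#' The split is by plot, so all stage records of a plot fall on the same
#' side (no temporal leakage). With a plot count not divisible by 3 the
#' nearest 2:1 split is taken with a warning.
#'
#' @param plot_ids Vector of plot identifiers (duplicates collapsed).
#' @param seed Integer seed; the assignment is reproducible.
#' @return List with `cali` and `vali` plot-id vectors.
#' @export
split_2to1 <- function(plot_ids, seed = 1L) {
  ids <- sort(unique(plot_ids))
  n <- length(ids)
  if (n < 6L) stop("need at least 6 plots to split 2:1")
  if (n %% 3L != 0L)
    warning("plot count ", n, " not divisible by 3; using nearest split")
  n_cali <- round(2 * n / 3)
  cali <- with_seed(seed, sort(sample(ids, n_cali)))
  list(cali = cali, vali = setdiff(ids, cali))
}

# p-value of each non-intercept coefficient of an lm fit; aliased
# (collinear) terms count as p = 1.
.term_pvalues <- function(fit) {
  cf <- summary(fit)$coefficients
  terms <- attr(stats::terms(fit), "term.labels")
  p <- stats::setNames(rep(1, length(terms)), terms)
  rn <- intersect(rownames(cf), terms)
  p[rn] <- cf[rn, 4L]
  p[is.na(p)] <- 1
  p
}

#' Multiple stepwise regression
#'
#' Bidirectional p-value stepwise least squares: at each round the
#' candidate with the smallest entry p-value below `p_enter` joins the
#' model, then any retained term with p-value above `p_remove` is dropped
#' (worst first), until a fixed point. Ties in p-value break by
#' lexicographic candidate name, so the result is deterministic and
#' independent of candidate ordering.
#'
#' @param features Data frame with a `lai` column and the candidates.
#' @param candidates Candidate feature column names (>= 1).
#' @param p_enter Entry threshold (default 0.05).
#' @param p_remove Removal threshold (default 0.10).
#' @param max_steps Safety cap on add/remove rounds.
#' @return A [lai_equation] (intercept-only, with a warning, when no
#'   candidate passes entry).
#' @export
fit_msr <- function(features, candidates, p_enter = 0.05,
                    p_remove = 0.10, max_steps = 100L) {
  if (length(candidates) < 1L) stop("need at least one candidate")
  missing_cols <- setdiff(c("lai", candidates), names(features))
  if (length(missing_cols) > 0L)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  dat <- features[, c("lai", candidates), drop = FALSE]
  cc <- stats::complete.cases(dat) &
    apply(is.finite(as.matrix(dat)), 1L, all)
  dat <- dat[cc, , drop = FALSE]
  if (nrow(dat) < length(candidates) + 2L && nrow(dat) < 10L)
    stop("too few complete records (", nrow(dat), ") for stepwise fit")
  candidates <- sort(candidates)
  selected <- character(0)
  seen <- character(0)
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    ## entry
    pool <- setdiff(candidates, selected)
    if (length(pool) > 0L) {
      entry_p <- vapply(pool, function(cand) {
        f <- stats::reformulate(c(selected, cand), response = "lai")
        .term_pvalues(lm(f, data = dat))[[cand]]
      }, numeric(1))
      ord <- order(entry_p, pool)
      if (entry_p[ord[1L]] < p_enter) {
        selected <- c(selected, pool[ord[1L]])
        changed <- TRUE
      }
    }
    ## removal
    repeat {
      if (length(selected) == 0L) break
      f <- stats::reformulate(selected, response = "lai")
      p <- .term_pvalues(lm(f, data = dat))
      worst <- names(p)[order(-p, names(p))][1L]
      if (p[[worst]] > p_remove) {
        selected <- setdiff(selected, worst)
        changed <- TRUE
      } else break
    }
    key <- paste(sort(selected), collapse = "|")
    if (!changed || key %in% seen) break
    seen <- c(seen, key)
  }
  if (length(selected) == 0L) {
    warning("no candidate passed the entry threshold; intercept-only model")
    return(lai_equation(mean(dat$lai)))
  }
  fit <- lm(stats::reformulate(selected, response = "lai"), data = dat)
  cf <- coef(fit)
  lai_equation(unname(cf["(Intercept)"]),
               coefficients = unname(cf[selected]), features = selected)
}

#' Random-forest LAI model
#'
#' Bagged regression trees with random feature subsets
#' (`randomForest`, 500 trees, `ceiling(m/3)` features per split),
#' seeded for reproducibility. A degenerate constant response yields a
#' constant predictor.
#'
#' @param features Data frame with `lai` and the candidates.
#' @param candidates Candidate feature column names.
#' @param n_trees Number of trees.
#' @param seed Integer seed.
#' @return An object of class `"lai_rf"` usable with [predict] and
#'   [evaluate_model].
#' @export
fit_rf <- function(features, candidates, n_trees = 500L, seed = 1L) {
  missing_cols <- setdiff(c("lai", candidates), names(features))
  if (length(missing_cols) > 0L)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  dat <- features[, c("lai", candidates), drop = FALSE]
  cc <- stats::complete.cases(dat) &
    apply(is.finite(as.matrix(dat)), 1L, all)
  dat <- dat[cc, , drop = FALSE]
  candidates <- sort(candidates)
  if (stats::sd(dat$lai) == 0) {
    return(structure(list(constant = dat$lai[1L], candidates = candidates),
                     class = "lai_rf"))
  }
  rf <- with_seed(seed,
    randomForest::randomForest(
      x = dat[, candidates, drop = FALSE], y = dat$lai,
      ntree = n_trees, mtry = max(1L, ceiling(length(candidates) / 3))))
  structure(list(rf = rf, candidates = candidates), class = "lai_rf")
}

#' @export
predict.lai_rf <- function(object, newdata, ...) {
  if (!is.null(object$constant))
    return(rep(object$constant, nrow(newdata)))
  unname(stats::predict(object$rf,
                        newdata[, object$candidates, drop = FALSE]))
}

#' Accuracy metrics of an LAI model
#'
#' `R^2 = 1 - SS_res / SS_tot`, root mean square error, and mean absolute
#' error of predictions against measured LAI.
#'
#' @param model A [lai_equation], an `"lai_rf"`, or anything with a
#'   `predict(model, newdata)` method returning LAI.
#' @param records Data frame with `lai` and the model's features.
#' @return Named numeric: `r2`, `rmse`, `mae`, `n`. Zero LAI variance
#'   reports `r2 = NA` with a warning.
#' @export
evaluate_model <- function(model, records) {
  if (nrow(records) == 0L) stop("no records to evaluate on")
  pred <- if (inherits(model, "lai_equation"))
    evaluate_equation(model, records) else predict(model, records)
  y <- records$lai
  ok <- is.finite(pred) & is.finite(y)
  pred <- pred[ok]; y <- y[ok]
  if (length(y) == 0L) stop("no finite prediction/measurement pairs")
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    warning("zero LAI variance; R2 undefined")
    NA_real_
  } else 1 - ss_res / ss_tot
  c(r2 = r2, rmse = sqrt(mean((y - pred)^2)),
    mae = mean(abs(y - pred)), n = length(y))
}

#' Compare feature sets and algorithms on one plot split
#'
#' Fits multiple stepwise regression and/or random forest on the
#' calibration plots for each named candidate set and evaluates on both
#' sides of the split.
#'
#' @param features Feature table with `plot_id`, `stage`, `lai` and all
#'   candidate columns.
#' @param feature_sets Named list of candidate name vectors, e.g.
#'   `list(si = ..., texture = ..., si_texture = ...)`.
#' @param split A [split_2to1] result.
#' @param algorithms Subset of `c("msr", "rf")`.
#' @param seed Seed for the random forest.
#' @return List with `metrics` (one row per algorithm x set x dataset) and
#'   `equations` (fitted [lai_equation] per stepwise set, rendered in the
#'   `LAI=...` notation in the metrics table).
#' @export
compare_feature_sets <- function(features, feature_sets,
                                 split = split_2to1(features$plot_id),
                                 algorithms = c("msr", "rf"), seed = 1L) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  cali <- features[features$plot_id %in% split$cali, , drop = FALSE]
  vali <- features[features$plot_id %in% split$vali, , drop = FALSE]
  rows <- list(); equations <- list()
  for (alg in algorithms) {
    for (set_name in names(feature_sets)) {
      cand <- feature_sets[[set_name]]
      model <- if (alg == "msr") fit_msr(cali, cand) else
        fit_rf(cali, cand, seed = seed)
      eq_txt <- if (alg == "msr") {
        equations[[set_name]] <- model
        render_equation(model)
      } else NA_character_
      for (ds in c("cali", "vali")) {
        m <- evaluate_model(model, if (ds == "cali") cali else vali)
        rows[[length(rows) + 1L]] <- data.frame(
          algorithm = alg, set = set_name, dataset = ds,
          r2 = unname(m["r2"]), rmse = unname(m["rmse"]),
          mae = unname(m["mae"]), n = unname(m["n"]),
          equation = eq_txt)
      }
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  list(metrics = metrics, equations = equations)
}
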