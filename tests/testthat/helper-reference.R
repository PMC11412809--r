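# Independent naive references used as oracles in the tests. These are
# deliberately written as plain double loops, with no code shared with the
# package implementations.

naive_glcm <- function(q, levels, offset = c(1L, 0L), symmetric = TRUE) {
  P <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  for (r in seq_len(nr)) {
    for (cl in seq_len(nc)) {
      r2 <- r + offset[1L]; c2 <- cl + offset[2L]
      if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
      a <- q[r, cl]; b <- q[r2, c2]
      if (is.na(a) || is.na(b)) next
      P[a + 1L, b + 1L] <- P[a + 1L, b + 1L] + 1
      if (symmetric) P[b + 1L, a + 1L] <- P[b + 1L, a + 1L] + 1
    }
  }
  P / sum(P)
}

naive_haralick <- function(P) {
  L <- nrow(P)
  mea <- 0; muy <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) {
    mea <- mea + (i - 1) * P[i, j]
    muy <- muy + (j - 1) * P[i, j]
  }
  varx <- 0; vary <- 0; hom <- 0; con <- 0; dis <- 0; ent <- 0; sec <- 0
  cov <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) {
    p <- P[i, j]
    d <- (i - 1) - (j - 1)
    varx <- varx + ((i - 1) - mea)^2 * p
    vary <- vary + ((j - 1) - muy)^2 * p
    hom <- hom + p / (1 + d^2)
    con <- con + d^2 * p
    dis <- dis + abs(d) * p
    if (p > 0) ent <- ent - p * log(p)
    sec <- sec + p^2
    cov <- cov + ((i - 1) - mea) * ((j - 1) - muy) * p
  }
  cor <- if (varx <= 0 || vary <= 0) 1 else cov / sqrt(varx * vary)
  c(Mea = mea, Var = varx, Hom = hom, Con = con, Dis = dis, Ent = ent,
    Sec = sec, Cor = cor)
}

# A small random multispectral raster for resampling/index tests.
random_mca_raster <- function(nr = 60, nc = 60, seed = 1) {
  wl <- c("490", "520", "550", "570", "670", "680", "700", "720", "800",
          "850", "900", "950")
  v <- with_seed(seed, array(runif(nr * nc * 12), c(nr, nc, 12L)))
  lai_raster(v, wl, res_cm = 8, kind = "reflectance")
}

# A tiny field and parameter set for fast synthetic-scene tests.
tiny_layout <- function(n_plots = 6)
  build_layout(n_plots, plot_w_m = 2, plot_h_m = 2, buffer_cm = 48)
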