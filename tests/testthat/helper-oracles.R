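# Independent brute-force oracles and small fixture builders.

# Brute-force TPI pipeline: naive per-cell loops over a disc neighbourhood.
# Mirrors the documented definition, not the implementation (which uses
# offset accumulation).
brute_tpi <- function(dtm, radius_m = 56.42, inner_res = 10,
                      analysis_res = 30) {
  f1 <- round(inner_res / dtm$res)
  d10 <- coarsen_raster(dtm, f1, "mean")
  z <- d10$values
  nr <- nrow(z); nc <- ncol(z)
  r_cells <- radius_m / d10$res
  nb_mean_excl <- function(m, i, j, exclude_centre) {
    acc <- 0; cnt <- 0
    for (di in -ceiling(r_cells):ceiling(r_cells)) {
      for (dj in -ceiling(r_cells):ceiling(r_cells)) {
        if (di^2 + dj^2 > r_cells^2) next
        if (exclude_centre && di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (is.na(m[ii, jj])) next
        acc <- acc + m[ii, jj]; cnt <- cnt + 1
      }
    }
    if (cnt == 0) NA_real_ else acc / cnt
  }
  tpi10 <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    tpi10[i, j] <- z[i, j] - nb_mean_excl(z, i, j, TRUE)
  sm <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    sm[i, j] <- nb_mean_excl(tpi10, i, j, FALSE)
  coarsen_raster(raster_grid(sm, d10$res, d10$origin),
                 round(analysis_res / d10$res), "mean")
}

# Brute-force trailing window sums
brute_running_sum <- function(p, window) {
  n <- length(p)
  out <- rep(NA_real_, n)
  for (i in window:n) out[i] <- sum(p[(i - window + 1):i])
  out
}

# tiny raster helper
rg <- function(m, res = 30, origin = NULL) {
  m <- as.matrix(m)
  if (is.null(origin)) origin <- c(0, nrow(m) * res)
  raster_grid(m, res, origin)
}

# a small complete pixel table on an nr x nc 30 m grid
toy_pixel_table <- function(nr = 10, nc = 10, res = 30, seed = 1,
                            cover = NULL, density = NULL, delta = NULL) {
  set.seed(seed)
  mk <- function(v) rg(matrix(v, nr, nc), res)
  if (is.null(cover)) cover <- matrix(cover_classes[["forest"]], nr, nc)
  if (is.null(density)) density <- matrix(13, nr, nc)
  if (is.null(delta)) delta <- matrix(rnorm(nr * nc), nr, nc)
  t14 <- matrix(runif(nr * nc, 5, 40), nr, nc)
  cover_r <- rg(cover, res)
  d_edge <- if (any(cover == cover_classes[["oil_palm"]]))
    distance_to_edge(cover_r) else mk(matrix(500, nr, nc))
  assemble_pixel_table(mk(t14), mk(t14 + delta),
                       mk(matrix(rnorm(nr * nc), nr, nc)),
                       mk(matrix(rnorm(nr * nc, 8), nr, nc)),
                       d_edge, mk(density), cover_r)
}

# exhaustive per-cell evaluation of the filter flags (independent of the
# distance-transform implementation: O(n^2) pairwise distances)
brute_filter_flags <- function(table, control = filter_control()) {
  n <- nrow(table)
  dist2 <- function(i, j)
    (table$x[i] - table$x[j])^2 + (table$y[i] - table$y[j])^2
  near_class <- function(i, class, buf) {
    js <- which(table$cover == class)
    any(vapply(js, function(j) dist2(i, j) <= buf^2 + 1e-9, logical(1)))
  }
  flags <- replicate(n, character(0), simplify = FALSE)
  for (i in seq_len(n)) {
    if (control$exclude_non_forest &&
        table$cover[i] %in% c("oil_palm", "clearcut"))
      flags[[i]] <- c(flags[[i]], "non_forest")
    if (control$clearcut_buffer_m > 0 && table$cover[i] != "clearcut" &&
        near_class(i, "clearcut", control$clearcut_buffer_m))
      flags[[i]] <- c(flags[[i]], "clearcut_buffer")
    if (!is.na(control$road_buffer_m) && control$road_buffer_m >= 0 &&
        near_class(i, "road", control$road_buffer_m))
      flags[[i]] <- c(flags[[i]], "road_buffer")
    if (control$density_threshold > 0 &&
        !is.na(table$density_2014[i]) &&
        table$density_2014[i] < control$density_threshold)
      flags[[i]] <- c(flags[[i]], "low_density")
    if (is.na(table$delta_tch[i]) || is.na(table$tpi[i]) ||
        !is.finite(table$d_edge[i]))
      flags[[i]] <- c(flags[[i]], "nodata")
  }
  surv <- which(lengths(flags) == 0)
  if (control$trim_fraction > 0 && length(surv)) {
    k <- floor(control$trim_fraction * length(surv))
    if (k > 0) {
      r <- rank(table$delta_tch[surv], ties.method = "first")
      tr <- surv[r <= k | r > length(surv) - k]
      for (i in tr) flags[[i]] <- c(flags[[i]], "trimmed")
    }
  }
  flags
}

# small scene config for fast tests (caller overrides merged into the
# small-scene defaults block by block)
small_cfg <- function(seed = 1, ...) {
  base <- list(extent_m = c(2400, 2400),
               cover = list(n_clearcut_patches = 1,
                            clearcut_patch_radius_m = 100))
  args <- list(...)
  for (k in names(args))
    base[[k]] <- if (is.list(base[[k]]) && is.list(args[[k]]))
      modifyList(base[[k]], args[[k]]) else args[[k]]
  do.call(scene_config, c(list(seed = seed), base))
}

# generating coefficients used throughout
eq1_params <- c(beta0 = 0.6576, beta_tpi = -0.02142, beta_tch = -0.0172,
                b = 0.8553, c = 0.0049)

# synthetic pixel data drawn directly from the asymptotic model (iid noise)
simulate_eq2_rows <- function(n, sd = 0.9, seed = 1, params = eq1_params) {
  set.seed(seed)
  tpi <- rnorm(n, 0, 5)
  tch <- runif(n, 0, 64)
  d <- rexp(n, 1 / 600)
  mu <- params[["beta0"]] + params[["beta_tpi"]] * tpi +
    params[["beta_tch"]] * tch - params[["b"]] * exp(-params[["c"]] * d)
  tibble::tibble(x = runif(n, 0, 10000), y = runif(n, 0, 10000),
                 tch_2014 = tch, tch_2016 = tch + mu + rnorm(n, 0, sd),
                 delta_tch = tch_2016 - tch_2014, tpi = tpi,
                 twi = rnorm(n, 8), d_edge = d, density_2014 = 13,
                 cover = "forest", excluded_by = "")
}
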