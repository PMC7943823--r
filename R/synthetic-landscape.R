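#' Synthetic landscapes for the canopy-change analysis
#'
#' The generator produces seeded scenes with the statistical structure the
#' downstream analysis assumes: smooth terrain, oil-palm conversion of the
#' lowlands, clear-cut patches and roads, a logging-intensity gradient of
#' initial canopy heights, and a height-change surface equal to the
#' generating edge-effect model plus spatially correlated Gaussian noise.
#' Every stage draws from a named sub-stream of the master seed, so the same
#' [scene_config()] always reproduces the identical scene.
#'
#' @name synthetic_landscape
NULL

with_sub_seed <- function(seed, stream, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(sub_seed(seed, stream))
  expr
}

#' Generate terrain (DTM)
#'
#' The sum of two kernel-smoothed Gaussian random fields - a broad component
#' (the configured correlation length and relief amplitude) carrying the
#' regional hill-and-lowland structure, and a fine-scale component whose
#' default amplitude reproduces the ridge-and-valley relief of the study
#' landscape at the 1 ha scale - superimposed on a regional linear trend.
#' Setting `fine_amplitude_m = 0` gives a single smooth field.
#'
#' @param cfg a [scene_config()].
#' @return a [raster_grid()] of elevations (m) at the base resolution.
#' @export
generate_terrain <- function(cfg) {
  cfg <- validate_scene_config(cfg)
  res <- cfg$base_resolution_m
  nr <- round(cfg$extent_m[2] / res); nc <- round(cfg$extent_m[1] / res)
  if (nr < 1 || nc < 1) stop("extent smaller than one cell")
  field <- with_sub_seed(cfg$seed, "terrain",
    sim_smoothed_field(nr, nc, res, cfg$terrain$correlation_length_m,
                       cfg$terrain$relief_amplitude_m) +
      sim_smoothed_field(nr, nc, res, cfg$terrain$fine_length_m,
                         cfg$terrain$fine_amplitude_m))
  x <- matrix((seq_len(nc) - 0.5) * res, nr, nc, byrow = TRUE)
  z <- cfg$terrain$base_elev_m + cfg$terrain$trend_slope * x + field
  raster_grid(z, res, c(0, nr * res))
}

#' Generate land cover from terrain
#'
#' Cells below the configured elevation quantile become oil palm (the
#' lowlands of the study region are almost entirely converted); circular
#' clear-cut patches and straight north-south roads of the configured width
#' are then stamped into the remaining forest.
#'
#' @param dtm a [raster_grid()] from [generate_terrain()].
#' @param cfg a [scene_config()].
#' @return a [raster_grid()] of [cover_classes] codes at the base resolution.
#' @export
generate_land_cover <- function(dtm, cfg) {
  cfg <- validate_scene_config(cfg)
  z <- dtm$values
  nr <- nrow(z); nc <- ncol(z)
  cov <- matrix(cover_classes[["forest"]], nr, nc)
  q <- cfg$cover$oil_palm_elev_quantile
  if (q > 0) {
    thr <- stats::quantile(z, q, na.rm = TRUE, names = FALSE)
    cov[z < thr] <- cover_classes[["oil_palm"]]
  }
  cc <- cell_centres(dtm)
  with_sub_seed(cfg$seed, "cover", {
    npatch <- cfg$cover$n_clearcut_patches
    if (npatch > 0) {
      forest_idx <- which(cov == cover_classes[["forest"]])
      centres <- sample(forest_idx, min(npatch, length(forest_idx)))
      for (ci in centres) {
        d2 <- (cc$x - cc$x[ci])^2 + (cc$y - cc$y[ci])^2
        stamp <- d2 <= cfg$cover$clearcut_patch_radius_m^2 &
          cov == cover_classes[["forest"]]
        cov[stamp] <- cover_classes[["clearcut"]]
      }
    }
    spacing <- cfg$cover$road_spacing_m
    if (is.finite(spacing) && spacing > 0 &&
        spacing <= cfg$extent_m[1]) {
      offset <- stats::runif(1, 0, spacing)
      road_x <- seq(offset, cfg$extent_m[1], by = spacing)
      half <- cfg$cover$road_width_m / 2
      for (rx in road_x) {
        band <- abs(cc$x - rx) <= half & cov == cover_classes[["forest"]]
        cov[band] <- cover_classes[["road"]]
      }
    }
  })
  cov[is.na(z)] <- NA_integer_
  raster_grid(cov, dtm$res, dtm$origin)
}

#' Generate the repeat-survey canopy height pair
#'
#' The initial canopy height surface is a monotone transform of a smooth
#' logging-intensity field, spanning the configured height envelope (0-64 m
#' by default: bare salvage-logged ground through tall remnant forest). The
#' height-change surface is the deterministic generating model (intercept,
#' TPI and initial-height terms minus an exponentially decaying edge
#' penalty) plus Gaussian noise split between a spatially correlated
#' component with an exponential correlogram and an uncorrelated nugget.
#' The second-survey surface is their sum.
#'
#' @param dtm base-resolution DTM.
#' @param cover base-resolution cover raster.
#' @param cfg a [scene_config()].
#' @param tpi,d_edge optional precomputed 30 m rasters (computed here when
#'   omitted).
#' @return list with 30 m rasters `tch_2014`, `tch_2016`, `delta`, `truth`
#'   (the noise-free change surface), `tpi`, `d_edge`, `cover` (30 m), and
#'   the generating coefficients under `$generating_model`.
#' @export
generate_canopy_pair <- function(dtm, cover, cfg, tpi = NULL, d_edge = NULL) {
  cfg <- validate_scene_config(cfg)
  fac <- round(cfg$analysis_resolution_m / cfg$base_resolution_m)
  cover30 <- coarsen_cover(cover, fac)
  if (!any(cover30$values == cover_classes[["oil_palm"]], na.rm = TRUE))
    stop("cover contains no oil_palm cells; distance to edge is undefined")
  if (is.null(tpi)) tpi <- compute_tpi(dtm,
    analysis_resolution_m = cfg$analysis_resolution_m)
  if (is.null(d_edge)) d_edge <- distance_to_edge(cover30)
  nr <- nrow(tpi$values); nc <- ncol(tpi$values)
  res30 <- cfg$analysis_resolution_m

  intensity <- with_sub_seed(cfg$seed, "logging",
    sim_smoothed_field(nr, nc, res30, cfg$canopy$logging_gradient_length_m, 1))
  u <- stats::pnorm(intensity)
  tch14 <- raster_grid(cfg$canopy$tch_min_m +
                         (cfg$canopy$tch_max_m - cfg$canopy$tch_min_m) * u,
                       res30, tpi$origin)

  gm <- cfg$generating_model
  truth_v <- gm$beta0 + gm$beta_tpi * tpi$values +
    gm$beta_tch * tch14$values -
    gm$edge_amp * exp(-gm$edge_rate * d_edge$values)

  sd_m <- cfg$noise$sd_m
  noise <- with_sub_seed(cfg$seed, "noise", {
    sp <- sim_grf_exp(nr, nc, res30, cfg$noise$spatial_range_m,
                      sd_m * sqrt(1 - cfg$noise$nugget_fraction))
    ng <- matrix(stats::rnorm(nr * nc,
                              sd = sd_m * sqrt(cfg$noise$nugget_fraction)),
                 nr, nc)
    sp + ng
  })
  delta_v <- truth_v + noise
  list(tch_2014 = tch14,
       tch_2016 = raster_grid(tch14$values + delta_v, res30, tpi$origin),
       delta = raster_grid(delta_v, res30, tpi$origin),
       truth = raster_grid(truth_v, res30, tpi$origin),
       tpi = tpi, d_edge = d_edge, cover = cover30,
       generating_model = gm)
}

#' Generate LiDAR point density and the density-biased height surface
#'
#' Point density is lognormal around the first survey's mean; canopy height
#' is underestimated where density falls below the threshold, with an
#' additive negative bias linear in the shortfall (zero at and above the
#' threshold). This emulates the documented underestimation of tree height
#' at low return densities.
#'
#' @param cfg a [scene_config()].
#' @param tch_2014 30 m initial-height raster to which the bias is applied.
#' @return list with rasters `density` (pts per m2), `bias` (m, all <= 0) and
#'   `tch_2014_biased`.
#' @export
generate_point_density <- function(cfg, tch_2014) {
  cfg <- validate_scene_config(cfg)
  m <- cfg$density$mean_pts_m2; s <- cfg$density$sd_pts_m2
  nr <- nrow(tch_2014$values); nc <- ncol(tch_2014$values)
  dens_v <- with_sub_seed(cfg$seed, "density", {
    if (s == 0) matrix(m, nr, nc) else {
      sdlog <- sqrt(log(1 + (s / m)^2))
      meanlog <- log(m) - sdlog^2 / 2
      matrix(stats::rlnorm(nr * nc, meanlog, sdlog), nr, nc)
    }
  })
  thr <- cfg$density$threshold_pts_m2
  bias_v <- -cfg$density$bias_slope_m_per_pt * pmax(0, thr - dens_v)
  list(density = raster_grid(dens_v, tch_2014$res, tch_2014$origin),
       bias = raster_grid(bias_v, tch_2014$res, tch_2014$origin),
       tch_2014_biased = raster_grid(tch_2014$values + bias_v,
                                     tch_2014$res, tch_2014$origin))
}

#' Generate a complete synthetic scene
#'
#' Runs terrain, cover, terrain metrics, the canopy pair, point density and
#' (optionally) plot censuses and climate, returning everything the
#' downstream pipeline consumes.
#'
#' @param cfg a [scene_config()].
#' @param include_aux also generate plot censuses and the climate series.
#' @return an object of class `landscape_scene`.
#' @export
generate_scene <- function(cfg, include_aux = FALSE) {
  cfg <- validate_scene_config(cfg)
  dtm <- generate_terrain(cfg)
  cover <- generate_land_cover(dtm, cfg)
  tpi <- compute_tpi(dtm, analysis_resolution_m = cfg$analysis_resolution_m)
  twi <- compute_twi(dtm, analysis_resolution_m = cfg$analysis_resolution_m)
  pair <- generate_canopy_pair(dtm, cover, cfg, tpi = tpi)
  dens <- generate_point_density(cfg, pair$tch_2014)
  scene <- list(config = cfg, dtm = dtm, cover = cover,
                cover30 = pair$cover, tpi = tpi, twi = twi,
                d_edge = pair$d_edge,
                tch_2014 = pair$tch_2014, tch_2016 = pair$tch_2016,
                delta = pair$delta, truth = pair$truth,
                density = dens$density,
                tch_2014_biased = dens$tch_2014_biased)
  if (include_aux) {
    scene$plots <- generate_plot_inventory(cfg)
    scene$climate <- generate_microclimate(cfg)
  }
  structure(scene, class = "landscape_scene")
}

#' @export
print.landscape_scene <- function(x, ...) {
  cat(sprintf("<landscape_scene> seed %d, %d x %d analysis cells @ %g m\n",
              x$config$seed, nrow(x$delta$values), ncol(x$delta$values),
              x$delta$res))
  tab <- table(factor(x$cover30$values, levels = cover_classes,
                      labels = names(cover_classes)))
  cat("  cover:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Simulate the analysis pixel table directly
#'
#' Convenience wrapper for recovery experiments: generates a scene, keeps the
#' forest-class analysis cells and returns them as a pixel table (see
#' [assemble_pixel_table()]), optionally subsampled without replacement to an
#' exact pixel count.
#'
#' @param cfg a [scene_config()].
#' @param n_pixels optional exact number of rows (seeded subsample; a warning
#'   is raised if fewer forest pixels are available).
#' @param use_biased_tch use the density-biased initial heights instead of
#'   the noise-free ones (default FALSE).
#' @return a tibble pixel table plus the scene as attribute `"scene"`.
#' @export
simulate_pixel_table <- function(cfg, n_pixels = NULL, use_biased_tch = FALSE) {
  scene <- generate_scene(cfg)
  tab <- assemble_pixel_table(
    tch_2014 = if (use_biased_tch) scene$tch_2014_biased else scene$tch_2014,
    tch_2016 = scene$tch_2016, tpi = scene$tpi, twi = scene$twi,
    d_edge = scene$d_edge, density = scene$density, cover = scene$cover30)
  tab <- tab[tab$cover == "forest" & is.finite(tab$d_edge), , drop = FALSE]
  if (!is.null(n_pixels)) {
    if (nrow(tab) < n_pixels)
      warning(sprintf("only %d forest pixels available (requested %d)",
                      nrow(tab), n_pixels))
    else {
      keep <- with_sub_seed(cfg$seed, "subset",
                            sample.int(nrow(tab), n_pixels))
      tab <- tab[sort(keep), , drop = FALSE]
    }
  }
  attr(tab, "scene") <- scene
  tab
}
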