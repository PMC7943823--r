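#' Interpolate a DTM from labelled ground returns
#'
#' Linear interpolation on the Delaunay triangulation of the ground-labelled
#' points (Bowyer-Watson triangulation, barycentric interpolation), sampled
#' at cell centres. Canopy returns never influence the terrain surface.
#' Cells outside the convex hull of the ground points are nodata.
#'
#' @param points data frame with columns `x`, `y`, `z` and logical
#'   `is_ground`.
#' @param res output resolution (m), default 1 m.
#' @param origin,nrow,ncol optional output frame; by default the bounding box
#'   of all points, snapped to `res`.
#' @return a [raster_grid()] of ground elevations.
#' @export
grid_points_to_dtm <- function(points, res = 1, origin = NULL,
                               nrow = NULL, ncol = NULL) {
  g <- points[points$is_ground, , drop = FALSE]
  if (nrow(g) < 3) stop("need at least 3 ground points")
  tri <- delaunay_triangulate(g$x, g$y)
  if (nrow(tri) == 0) stop("ground points are collinear")
  if (is.null(origin)) {
    x0 <- floor(min(points$x) / res) * res
    y1 <- ceiling(max(points$y) / res) * res
    origin <- c(x0, y1)
  }
  if (is.null(ncol)) ncol <- ceiling((max(points$x) - origin[1]) / res)
  if (is.null(nrow)) nrow <- ceiling((origin[2] - min(points$y)) / res)
  out <- matrix(NA_real_, nrow, ncol)
  cx <- origin[1] + (seq_len(ncol) - 0.5) * res
  cy <- origin[2] - (seq_len(nrow) - 0.5) * res
  for (t in seq_len(base::nrow(tri))) {
    v <- tri[t, ]
    x1 <- g$x[v[1]]; y1 <- g$y[v[1]]; z1 <- g$z[v[1]]
    x2 <- g$x[v[2]]; y2 <- g$y[v[2]]; z2 <- g$z[v[2]]
    x3 <- g$x[v[3]]; y3 <- g$y[v[3]]; z3 <- g$z[v[3]]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(det) < 1e-12) next
    ci <- which(cx >= min(x1, x2, x3) - res & cx <= max(x1, x2, x3) + res)
    ri <- which(cy >= min(y1, y2, y3) - res & cy <= max(y1, y2, y3) + res)
    if (!length(ci) || !length(ri)) next
    px <- matrix(cx[ci], length(ri), length(ci), byrow = TRUE)
    py <- matrix(cy[ri], length(ri), length(ci))
    l1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / det
    l2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / det
    l3 <- 1 - l1 - l2
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    zz <- l1 * z1 + l2 * z2 + l3 * z3
    sub <- out[ri, ci, drop = FALSE]
    sub[inside] <- zz[inside]
    out[ri, ci] <- sub
  }
  raster_grid(out, res, origin)
}

# Bowyer-Watson Delaunay triangulation; returns a matrix of vertex index
# triples. O(n^2), intended for the modest synthetic point sets used here.
delaunay_triangulate <- function(x, y) {
  n <- length(x)
  # super-triangle comfortably enclosing all points
  cxm <- mean(range(x)); cym <- mean(range(y))
  span <- max(diff(range(x)), diff(range(y)), 1) * 20
  px <- c(x, cxm - span, cxm + span, cxm)
  py <- c(y, cym - span / 2, cym - span / 2, cym + span)
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), ncol = 3)
  circ <- matrix(circumcircle(px, py, tris[1, ]), ncol = 3)
  for (i in seq_len(n)) {
    d2 <- (px[i] - circ[, 1])^2 + (py[i] - circ[, 2])^2
    bad <- which(d2 <= circ[, 3] * (1 + 1e-12))
    if (!length(bad)) next   # numerically degenerate; point skipped
    edges <- do.call(rbind, lapply(bad, function(t) {
      v <- tris[t, ]
      rbind(sort(c(v[1], v[2])), sort(c(v[2], v[3])), sort(c(v[1], v[3])))
    }))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    circ <- circ[-bad, , drop = FALSE]
    if (base::nrow(boundary)) {
      newt <- cbind(boundary, i)
      newc <- t(apply(newt, 1, function(v) circumcircle(px, py, v)))
      ok <- is.finite(newc[, 3])
      tris <- rbind(tris, newt[ok, , drop = FALSE])
      circ <- rbind(circ, newc[ok, , drop = FALSE])
    }
  }
  keep <- apply(tris <= n, 1, all)
  tris[keep, , drop = FALSE]
}

# circumcentre (cx, cy) and squared radius of triangle v (indices into px/py)
circumcircle <- function(px, py, v) {
  ax <- px[v[1]]; ay <- py[v[1]]
  bx <- px[v[2]]; by <- py[v[2]]
  cx <- px[v[3]]; cy <- py[v[3]]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(c(NA_real_, NA_real_, Inf))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  c(ux, uy, (ax - ux)^2 + (ay - uy)^2)
}

#' Build a canopy height model from labelled returns
#'
#' Per output cell, the maximum of (return elevation minus local terrain)
#' over the non-ground returns falling in the cell; negative heights are
#' clamped to zero; cells without canopy returns are nodata. Terrain is
#' sampled from the DTM cell containing each return.
#'
#' @param points data frame with `x`, `y`, `z`, `is_ground`.
#' @param dtm a [raster_grid()] covering the point extent.
#' @param res CHM resolution (m), default 2 m.
#' @return a [raster_grid()] CHM.
#' @export
build_chm <- function(points, dtm, res = 2) {
  p <- points[!points$is_ground, , drop = FALSE]
  nr_d <- nrow(dtm$values); nc_d <- ncol(dtm$values)
  drow <- floor((dtm$origin[2] - p$y) / dtm$res) + 1
  dcol <- floor((p$x - dtm$origin[1]) / dtm$res) + 1
  ok <- drow >= 1 & drow <= nr_d & dcol >= 1 & dcol <= nc_d
  if (!all(ok)) stop("DTM does not cover the point extent")
  ground <- dtm$values[cbind(drow, dcol)]
  h <- pmax(0, p$z - ground)
  nc <- ceiling(nc_d * dtm$res / res); nr <- ceiling(nr_d * dtm$res / res)
  row <- floor((dtm$origin[2] - p$y) / res) + 1
  col <- floor((p$x - dtm$origin[1]) / res) + 1
  keep <- !is.na(h) & row >= 1 & row <= nr & col >= 1 & col <= nc
  idx <- (col[keep] - 1L) * nr + row[keep]
  out <- matrix(NA_real_, nr, nc)
  if (length(idx)) {
    mx <- tapply(h[keep], idx, max)
    out[as.integer(names(mx))] <- as.numeric(mx)
  }
  raster_grid(out, res, dtm$origin)
}

#' Mean top-of-canopy height at the analysis resolution
#'
#' Block mean of the fine-resolution CHM (by default the 15 x 15 block of
#' 2 m cells inside each 30 m pixel). A pixel is valid only when at least
#' half of its sub-cells are valid, keeping partially clouded or sparsely
#' covered pixels out of the analysis.
#'
#' @param chm a [raster_grid()] CHM.
#' @param analysis_resolution_m output resolution (default 30 m).
#' @param min_valid_frac minimum valid sub-cell fraction (default 0.5).
#' @return a [raster_grid()] of TCH.
#' @export
tch_from_chm <- function(chm, analysis_resolution_m = 30,
                         min_valid_frac = 0.5) {
  f <- analysis_resolution_m / chm$res
  if (abs(f - round(f)) > 1e-9)
    stop("CHM resolution does not divide the analysis resolution")
  coarsen_raster(chm, round(f), "mean", min_valid_frac = min_valid_frac)
}

#' Assemble the per-pixel analysis table
#'
#' One row per 30 m cell, combining both height surveys, the terrain
#' metrics, distance to the plantation edge, point density and the cover
#' class. `delta_tch` is exactly `tch_2016 - tch_2014`. Exclusion flags start
#' empty; [apply_filter_ledger()] fills them.
#'
#' @param tch_2014,tch_2016,tpi,twi,d_edge,density,cover aligned 30 m
#'   [raster_grid()]s (`cover` holds [cover_classes] codes).
#' @return tibble with columns `x`, `y`, `tch_2014`, `tch_2016`, `delta_tch`,
#'   `tpi`, `twi`, `d_edge`, `density_2014`, `cover`, `excluded_by`.
#' @export
assemble_pixel_table <- function(tch_2014, tch_2016, tpi, twi, d_edge,
                                 density, cover) {
  rasters <- list(tch_2014 = tch_2014, tch_2016 = tch_2016, tpi = tpi,
                  twi = twi, d_edge = d_edge, density = density,
                  cover = cover)
  for (nm in names(rasters))
    if (!rasters_aligned(rasters[[nm]], tch_2014))
      stop("raster `", nm, "` is not aligned with tch_2014 ",
           "(origin/resolution/dimensions differ)")
  cc <- cell_centres(tch_2014)
  v14 <- as.vector(tch_2014$values); v16 <- as.vector(tch_2016$values)
  tibble::tibble(
    x = as.vector(cc$x), y = as.vector(cc$y),
    tch_2014 = v14, tch_2016 = v16, delta_tch = v16 - v14,
    tpi = as.vector(tpi$values), twi = as.vector(twi$values),
    d_edge = as.vector(d_edge$values),
    density_2014 = as.vector(density$values),
    cover = names(cover_classes)[match(as.vector(cover$values),
                                       cover_classes)],
    excluded_by = "")
}

#' Filtering controls for the pixel ledger
#'
#' @param exclude_non_forest drop oil-palm and clear-cut pixels.
#' @param clearcut_buffer_m buffer around clear-cut pixels (200 m; 0 or
#'   `FALSE`-ish disables).
#' @param road_buffer_m buffer around road pixels, road pixels included
#'   (30 m).
#' @param density_threshold minimum first-survey point density (pts per m2).
#' @param trim_fraction symmetric tail fraction of `delta_tch` trimmed from
#'   the surviving rows (0.01 = lower and upper 1%).
#' @return a list of class `filter_control`.
#' @export
filter_control <- function(exclude_non_forest = TRUE,
                           clearcut_buffer_m = 200,
                           road_buffer_m = 30,
                           density_threshold = 10,
                           trim_fraction = 0.01) {
  stopifnot(trim_fraction >= 0, trim_fraction < 0.5)
  structure(list(exclude_non_forest = exclude_non_forest,
                 clearcut_buffer_m = clearcut_buffer_m,
                 road_buffer_m = road_buffer_m,
                 density_threshold = density_threshold,
                 trim_fraction = trim_fraction),
            class = "filter_control")
}

# rebuild a matrix of one column of the (regular-grid) pixel table
table_to_matrix <- function(table, col) {
  xs <- sort(unique(table$x)); ys <- sort(unique(table$y), decreasing = TRUE)
  m <- matrix(NA_real_, length(ys), length(xs))
  ri <- match(table$y, ys); ci <- match(table$x, xs)
  m[cbind(ri, ci)] <- as.numeric(table[[col]])
  list(m = m, ri = ri, ci = ci, res = if (length(xs) > 1) min(diff(xs)) else 1)
}

#' Apply the pixel filtering ledger
#'
#' Recomputes every exclusion flag from scratch, in the fixed order the
#' analysis prescribes: (1) non-forest cover (oil palm, clear-cut);
#' (2) pixels within 200 m of any clear-cut pixel; (3) road pixels and
#' pixels within 30 m of one; (4) first-survey point density below
#' 10 pts per m2; (5) trimming of the lower and upper 1% of `delta_tch`
#' among the rows surviving (1)-(4) (by rank: the `floor(f * n)` most extreme
#' rows in each tail). Buffer distances are Euclidean between cell centres.
#' Because flags are recomputed, applying the ledger twice yields the
#' identical table and an all-zero second audit.
#'
#' @param table a pixel table from [assemble_pixel_table()].
#' @param control a [filter_control()].
#' @return list with `table` (flags filled) and `audit`, a tibble of
#'   (rule, removed, remaining) in application order, where `removed` counts
#'   rows that were analysis rows on entry.
#' @export
apply_filter_ledger <- function(table, control = filter_control()) {
  if (nrow(table) == 0) stop("empty pixel table")
  was_analysis <- table$excluded_by == ""
  flags <- vector("list", nrow(table))
  add_flag <- function(flags, which, name) {
    flags[which] <- lapply(flags[which], function(f) c(f, name))
    flags
  }
  flag_oil <- control$exclude_non_forest & table$cover == "oil_palm"
  flag_cc <- control$exclude_non_forest & table$cover == "clearcut"
  flags <- add_flag(flags, which(flag_oil | flag_cc), "non_forest")

  geom <- table_to_matrix(table, "delta_tch")   # frame only
  buffer_flag <- function(class, dist_m) {
    mask <- matrix(FALSE, nrow(geom$m), ncol(geom$m))
    mask[cbind(geom$ri, geom$ci)] <- table$cover == class
    if (!any(mask)) return(rep(FALSE, nrow(table)))
    d <- distance_transform(mask) * geom$res
    d[cbind(geom$ri, geom$ci)] <= dist_m
  }
  flag_ccb <- if (isTRUE(control$clearcut_buffer_m > 0))
    buffer_flag("clearcut", control$clearcut_buffer_m) else
      rep(FALSE, nrow(table))
  flag_ccb <- flag_ccb & table$cover != "clearcut"   # patch itself is rule 1
  flags <- add_flag(flags, which(flag_ccb), "clearcut_buffer")

  rb <- control$road_buffer_m
  flag_road <- if (!is.null(rb) && !is.na(rb) && rb >= 0)
    buffer_flag("road", rb) else rep(FALSE, nrow(table))
  flags <- add_flag(flags, which(flag_road), "road_buffer")

  flag_dens <- if (!is.null(control$density_threshold) &&
                   control$density_threshold > 0)
    !is.na(table$density_2014) &
      table$density_2014 < control$density_threshold else
        rep(FALSE, nrow(table))
  flags <- add_flag(flags, which(flag_dens), "low_density")

  flag_na <- is.na(table$delta_tch) | is.na(table$tpi) |
    !is.finite(table$d_edge)
  flags <- add_flag(flags, which(flag_na), "nodata")

  pre_trim <- !(flag_oil | flag_cc | flag_ccb | flag_road | flag_dens |
                  flag_na)
  flag_trim <- rep(FALSE, nrow(table))
  if (control$trim_fraction > 0 && any(pre_trim)) {
    idx <- which(pre_trim)
    k <- floor(control$trim_fraction * length(idx))
    if (k > 0) {
      r <- rank(table$delta_tch[idx], ties.method = "first")
      flag_trim[idx[r <= k | r > length(idx) - k]] <- TRUE
    }
  }
  flags <- add_flag(flags, which(flag_trim), "trimmed")

  out <- table
  out$excluded_by <- vapply(flags, function(f)
    if (is.null(f)) "" else paste(f, collapse = ","), character(1))

  steps <- list(non_forest = flag_oil | flag_cc, clearcut_buffer = flag_ccb,
                road_buffer = flag_road, low_density = flag_dens,
                nodata = flag_na, trimmed = flag_trim)
  removed <- integer(length(steps)); remaining <- integer(length(steps))
  still <- was_analysis
  for (i in seq_along(steps)) {
    newly <- still & steps[[i]]
    removed[i] <- sum(newly)
    still <- still & !steps[[i]]
    remaining[i] <- sum(still)
  }
  list(table = out,
       audit = tibble::tibble(rule = names(steps), removed = removed,
                              remaining = remaining))
}

#' Analysis rows of a pixel table
#'
#' @param table a pixel table.
#' @return the rows whose `excluded_by` is empty.
#' @export
analysis_rows <- function(table) {
  table[table$excluded_by == "", , drop = FALSE]
}
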