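#' Land-cover class codes
#'
#' Cover rasters store integer codes; this named vector fixes the coding
#' shared by the generator, the terrain metrics and the filtering ledger.
#' @export
cover_classes <- c(forest = 1L, oil_palm = 2L, clearcut = 3L, road = 4L)

# sum / count of values over a disc neighbourhood, truncated at the borders.
# Returns list(sum, count) where count excludes NA cells. Centre included;
# callers subtract it when the neighbourhood must exclude the focal cell.
disc_sums <- function(m, radius_cells) {
  nr <- nrow(m); nc <- ncol(m)
  r <- floor(radius_cells)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius_cells^2, ]
  valid <- !is.na(m)
  m0 <- m; m0[!valid] <- 0
  sums <- matrix(0, nr, nc); cnts <- matrix(0L, nr, nc)
  for (k in seq_len(nrow(offs))) {
    di <- offs$di[k]; dj <- offs$dj[k]
    ri <- max(1, 1 - di):min(nr, nr - di)
    ci <- max(1, 1 - dj):min(nc, nc - dj)
    sums[ri, ci] <- sums[ri, ci] + m0[ri + di, ci + dj, drop = FALSE]
    cnts[ri, ci] <- cnts[ri, ci] + valid[ri + di, ci + dj, drop = FALSE]
  }
  list(sum = sums, count = cnts)
}

#' Topographic position index at the analysis resolution
#'
#' TPI measures the elevation of a cell relative to its surrounding
#' landscape: positive on ridges and hilltops, negative in valleys. The
#' pipeline is: (1) coarsen the DTM to 10 m by spatial averaging; (2) at each
#' 10 m cell, TPI = elevation minus the mean elevation over a circular 1 ha
#' neighbourhood (radius 56.42 m), the focal cell excluded; (3) smooth by
#' taking the mean TPI within the same 1 ha neighbourhood; (4) block-average
#' to the analysis grid. Neighbourhoods are truncated at the raster border
#' (means use the cells actually present).
#'
#' @param dtm a [raster_grid()] DTM with resolution <= 10 m.
#' @param radius_m neighbourhood radius in metres; the default 56.42 m gives
#'   a 1 ha disc.
#' @param inner_resolution_m resolution of the intermediate TPI grid (10 m).
#' @param analysis_resolution_m output grid resolution (30 m).
#' @return a [raster_grid()] of TPI (m) at the analysis resolution.
#' @export
compute_tpi <- function(dtm, radius_m = 56.42, inner_resolution_m = 10,
                        analysis_resolution_m = 30) {
  if (dtm$res > inner_resolution_m + 1e-9)
    stop("DTM resolution must be <= ", inner_resolution_m, " m")
  f1 <- round(inner_resolution_m / dtm$res)
  if (abs(f1 * dtm$res - inner_resolution_m) > 1e-6)
    stop("DTM resolution must divide ", inner_resolution_m, " m")
  d10 <- coarsen_raster(dtm, f1, "mean")
  r_cells <- radius_m / d10$res
  if (min(dim(d10$values)) < r_cells)
    stop("DTM smaller than one TPI neighbourhood")
  z <- d10$values
  ds <- disc_sums(z, r_cells)
  valid <- !is.na(z)
  nb_mean <- (ds$sum - ifelse(valid, z, 0)) / (ds$count - valid)
  tpi10 <- z - nb_mean
  sm <- disc_sums(tpi10, r_cells)
  tpi_sm <- sm$sum / sm$count
  tpi_sm[!valid] <- NA_real_
  f2 <- round(analysis_resolution_m / d10$res)
  coarsen_raster(raster_grid(tpi_sm, d10$res, d10$origin), f2, "mean")
}

# Planchon-Darboux sink filling: raise each cell to the lowest spill level
# reachable from the border, with a small epsilon gradient across flats.
fill_sinks <- function(z, eps = 1e-3) {
  nr <- nrow(z); nc <- ncol(z)
  big <- max(z, na.rm = TRUE) + 1e6
  w <- matrix(big, nr, nc)
  border <- matrix(FALSE, nr, nc)
  border[1, ] <- border[nr, ] <- TRUE
  border[, 1] <- border[, nc] <- TRUE
  border[is.na(z)] <- FALSE
  # cells adjacent to nodata drain freely, like the border
  if (anyNA(z)) {
    na_adj <- disc_sums(ifelse(is.na(z), 1, 0), 1.5)$sum > 0
    border <- border | (na_adj & !is.na(z))
  }
  w[border] <- z[border]
  w[is.na(z)] <- NA_real_
  sh <- expand.grid(di = -1:1, dj = -1:1)
  sh <- sh[!(sh$di == 0 & sh$dj == 0), ]
  repeat {
    w_old <- w
    for (k in seq_len(nrow(sh))) {
      di <- sh$di[k]; dj <- sh$dj[k]
      ri <- max(1, 1 - di):min(nr, nr - di)
      ci <- max(1, 1 - dj):min(nc, nc - dj)
      cand <- pmax(z[ri, ci, drop = FALSE],
                   w[ri + di, ci + dj, drop = FALSE] + eps)
      cand[is.na(cand)] <- Inf          # nodata neighbours never drain
      cand[is.na(z[ri, ci])] <- NA_real_
      w[ri, ci] <- pmin(w[ri, ci, drop = FALSE], cand)
    }
    delta <- suppressWarnings(max(abs(w - w_old), na.rm = TRUE))
    if (!is.finite(delta) || delta < eps / 10) break
  }
  w
}

#' D8 flow accumulation
#'
#' Fills sinks (Planchon-Darboux with a small epsilon gradient), routes each
#' cell's flow to its steepest-descent neighbour among the 8 adjacent cells
#' (drop divided by centre-to-centre distance) and accumulates the number of
#' upslope cells, each cell counting itself. Cells with no lower neighbour
#' after filling drain off-grid.
#'
#' @param dtm a [raster_grid()] (typically the 30 m DTM).
#' @return list with `acc` (accumulated cell counts, matrix), `down` (linear
#'   index of the downstream cell, NA for outlets) and `filled` (sink-filled
#'   elevations).
#' @export
flow_accumulation <- function(dtm) {
  z <- dtm$values
  if (all(is.na(z))) stop("all-nodata DTM")
  w <- fill_sinks(z)
  nr <- nrow(w); nc <- ncol(w)
  sh <- expand.grid(di = -1:1, dj = -1:1)
  sh <- sh[!(sh$di == 0 & sh$dj == 0), ]
  best_slope <- matrix(-Inf, nr, nc)
  down <- matrix(NA_integer_, nr, nc)
  for (k in seq_len(nrow(sh))) {
    di <- sh$di[k]; dj <- sh$dj[k]
    dist <- sqrt(di^2 + dj^2) * dtm$res
    slope <- matrix(-Inf, nr, nc)
    ri <- max(1, 1 - di):min(nr, nr - di)
    ci <- max(1, 1 - dj):min(nc, nc - dj)
    slope[ri, ci] <- (w[ri, ci, drop = FALSE] -
                        w[ri + di, ci + dj, drop = FALSE]) / dist
    idx <- matrix(NA_integer_, nr, nc)
    idx[ri, ci] <- (rep(ci + dj, each = length(ri)) - 1L) * nr +
      rep(ri + di, length(ci))
    better <- !is.na(slope) & slope > best_slope & slope > 0
    best_slope[better] <- slope[better]
    down[better] <- idx[better]
  }
  down[is.na(z)] <- NA_integer_
  acc <- matrix(1, nr, nc)
  acc[is.na(z)] <- NA_real_
  ord <- order(w, decreasing = TRUE, na.last = NA)
  for (i in ord) {
    d <- down[i]
    if (!is.na(d) && !is.na(acc[d])) acc[d] <- acc[d] + acc[i]
  }
  list(acc = acc, down = down, filled = w)
}

#' Topographic wetness index
#'
#' TWI = ln(a / tan beta), where a is the specific catchment area (D8
#' accumulated cell count times cell area divided by cell width) and beta the
#' local slope from central differences (one-sided at the borders), floored
#' at `tan beta >= slope_floor` so flats stay finite. The DTM is coarsened to
#' the analysis resolution by spatial averaging before routing. High values
#' mark cells that accumulate soil moisture (valley floors); low values mark
#' shedding positions (ridges).
#'
#' @param dtm a [raster_grid()] DTM at or below the analysis resolution.
#' @param analysis_resolution_m output resolution (30 m).
#' @param slope_floor minimum tan(slope).
#' @return a [raster_grid()] of TWI at the analysis resolution.
#' @export
compute_twi <- function(dtm, analysis_resolution_m = 30, slope_floor = 1e-4) {
  if (all(is.na(dtm$values))) stop("all-nodata DTM")
  f <- round(analysis_resolution_m / dtm$res)
  if (f < 1) stop("DTM is coarser than the analysis resolution")
  d30 <- if (f > 1) coarsen_raster(dtm, f, "mean") else dtm
  z <- d30$values
  fa <- flow_accumulation(d30)
  res <- d30$res
  nr <- nrow(z); nc <- ncol(z)
  # central differences, one-sided at borders
  zx <- (z[, c(2:nc, nc), drop = FALSE] - z[, c(1, 1:(nc - 1)), drop = FALSE]) /
    (res * ifelse(matrix(seq_len(nc), nr, nc, byrow = TRUE) %in% c(1, nc), 1, 2))
  zy <- (z[c(2:nr, nr), , drop = FALSE] - z[c(1, 1:(nr - 1)), , drop = FALSE]) /
    (res * ifelse(matrix(seq_len(nr), nr, nc) %in% c(1, nr), 1, 2))
  tanb <- pmax(sqrt(zx^2 + zy^2), slope_floor)
  a <- fa$acc * res^2 / res
  twi <- log(a / tanb)
  twi[is.na(z)] <- NA_real_
  raster_grid(twi, res, d30$origin)
}

# exact 1-D squared distance transform (Felzenszwalb & Huttenlocher)
dt_1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n); v <- integer(n); zb <- numeric(n + 1)
  k <- 1L; v[1] <- 1L; zb[1] <- -Inf; zb[2] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
      if (s <= zb[k]) { k <- k - 1L } else break
    }
    k <- k + 1L
    v[k] <- q
    zb[k] <- s
    zb[k + 1] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (zb[k + 1] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# exact Euclidean distance transform (cell units) to the TRUE cells of mask
distance_transform <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  big <- 4 * (nr^2 + nc^2) + 10   # exceeds any attainable squared distance
  f <- matrix(ifelse(mask, 0, big), nr, nc)
  for (j in seq_len(nc)) f[, j] <- dt_1d(f[, j])
  for (i in seq_len(nr)) f[i, ] <- dt_1d(f[i, ])
  sqrt(f)
}

#' Distance from each cell to the nearest oil-palm cell
#'
#' Exact Euclidean distance transform, measured centre-to-centre on the
#' analysis grid; oil-palm cells themselves are at distance 0. When the cover
#' contains no oil-palm cell every distance is infinite (returned as `Inf`
#' with a warning), so downstream edge terms vanish.
#'
#' @param cover a [raster_grid()] of [cover_classes] codes at the analysis
#'   resolution.
#' @param class which class defines the edge (default `"oil_palm"`).
#' @return a [raster_grid()] of distances in metres.
#' @export
distance_to_edge <- function(cover, class = "oil_palm") {
  code <- cover_classes[[class]]
  mask <- !is.na(cover$values) & cover$values == code
  if (!any(mask)) {
    warning("no ", class, " cells in cover; returning all-Inf distances")
    return(raster_grid(matrix(Inf, nrow(cover$values), ncol(cover$values)),
                       cover$res, cover$origin))
  }
  d <- distance_transform(mask) * cover$res
  raster_grid(d, cover$res, cover$origin)
}

#' Coarsen a cover raster to the analysis grid
#'
#' Majority vote within each block, except that narrow high-impact classes
#' keep priority: a block becomes road if at least `priority_frac` of its
#' sub-cells are road, else clearcut by the same rule, else the plurality
#' class (ties broken in the order road > clearcut > oil_palm > forest).
#'
#' @param cover a [raster_grid()] of [cover_classes] codes.
#' @param factor integer block size.
#' @param priority_frac fraction at which road/clearcut pre-empt the majority.
#' @return a [raster_grid()] of codes at `factor` times the input resolution.
#' @export
coarsen_cover <- function(cover, factor, priority_frac = 0.3) {
  factor <- as.integer(factor)
  if (factor < 1) stop("`factor` must be a positive integer")
  if (factor == 1L) return(cover)
  fracs <- lapply(cover_classes, function(code) {
    ind <- raster_grid((cover$values == code) * 1, cover$res, cover$origin)
    coarsen_raster(ind, factor, "mean")$values
  })
  nr <- nrow(fracs[[1]]); nc <- ncol(fracs[[1]])
  out <- matrix(cover_classes[["forest"]], nr, nc)
  # plurality, ties to the rarer/more disruptive class
  stack <- simplify2array(fracs)           # nr x nc x 4
  ord <- c("road", "clearcut", "oil_palm", "forest")
  best <- apply(stack[, , ord, drop = FALSE], c(1, 2),
                function(v) ord[which.max(v)])
  out[] <- cover_classes[best]
  for (cl in c("clearcut", "road"))
    out[fracs[[cl]] >= priority_frac] <- cover_classes[[cl]]
  out[is.na(fracs[[1]])] <- NA_integer_
  raster_grid(out, cover$res * factor, cover$origin)
}
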