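#' Planar raster grids
#'
#' `raster_grid` is the package's spatial substrate: a rectangular matrix of
#' values on a planar metre grid. Storage is row-major with the origin at the
#' top-left corner and y increasing upward in world coordinates (so row 1 is
#' the northernmost row). Cell centres sit at `origin + (index - 0.5) * res`.
#' Missing cells are `NA`; the nodata sentinel only appears on disk.
#'
#' @param values numeric matrix (row 1 = top).
#' @param res cell size in metres (single positive number).
#' @param origin length-2 numeric, planar (x, y) of the top-left corner.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, res, origin = c(0, 0)) {
  values <- as.matrix(values)
  if (!is.numeric(res) || length(res) != 1 || !is.finite(res) || res <= 0)
    stop("`res` must be a single positive number (metres)")
  if (length(origin) != 2 || any(!is.finite(origin)))
    stop("`origin` must be finite (x, y) of the top-left corner")
  storage.mode(values) <- "double"
  structure(list(values = values, res = as.numeric(res),
                 origin = as.numeric(origin)),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d cells @ %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), x$res, x$origin[1], x$origin[2]))
  cat(sprintf("  values: [%g, %g], %d NA\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Cell-centre coordinates of a raster
#'
#' @param grid a [raster_grid()].
#' @return list with matrices `x` and `y` of cell-centre coordinates.
#' @export
cell_centres <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  x <- grid$origin[1] + (seq_len(nc) - 0.5) * grid$res
  y <- grid$origin[2] - (seq_len(nr) - 0.5) * grid$res
  list(x = matrix(x, nr, nc, byrow = TRUE), y = matrix(y, nr, nc))
}

# rasters share a grid frame if origin and resolution agree to sub-mm
rasters_aligned <- function(a, b) {
  isTRUE(all.equal(dim(a$values), dim(b$values))) &&
    abs(a$res - b$res) < 1e-9 && all(abs(a$origin - b$origin) < 1e-6)
}

#' Coarsen a raster by block aggregation
#'
#' Aggregates `factor` x `factor` blocks of cells into one output cell using
#' the block mean (ignoring `NA`) or the block maximum. When `factor` does not
#' divide the grid dimensions the grid is padded with `NA`; padded cells never
#' contribute to the statistic. An all-`NA` block yields `NA`.
#'
#' @param grid a [raster_grid()].
#' @param factor positive integer aggregation factor.
#' @param aggregator `"mean"` or `"max"`.
#' @param min_valid_frac minimum fraction of non-`NA` sub-cells for an output
#'   cell to be valid (default 0: any valid sub-cell suffices).
#' @return a [raster_grid()] with resolution `grid$res * factor`.
#' @export
coarsen_raster <- function(grid, factor, aggregator = c("mean", "max"),
                           min_valid_frac = 0) {
  aggregator <- match.arg(aggregator)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("`factor` must be a positive integer")
  m <- grid$values
  if (factor == 1L && min_valid_frac <= 0) return(grid)
  nr <- nrow(m); nc <- ncol(m)
  nr2 <- ceiling(nr / factor); nc2 <- ceiling(nc / factor)
  if (nr2 * factor != nr || nc2 * factor != nc) {
    pad <- matrix(NA_real_, nr2 * factor, nc2 * factor)
    pad[seq_len(nr), seq_len(nc)] <- m
    m <- pad
  }
  sums <- matrix(0, nr2, nc2)
  cnts <- matrix(0L, nr2, nc2)
  mx <- matrix(-Inf, nr2, nc2)
  for (di in seq_len(factor)) {
    ri <- seq(di, by = factor, length.out = nr2)
    for (dj in seq_len(factor)) {
      ci <- seq(dj, by = factor, length.out = nc2)
      sub <- m[ri, ci, drop = FALSE]
      ok <- !is.na(sub)
      cnts <- cnts + ok
      sub0 <- sub; sub0[!ok] <- 0
      sums <- sums + sub0
      subm <- sub; subm[!ok] <- -Inf
      mx <- pmax(mx, subm)
    }
  }
  out <- if (aggregator == "mean") sums / cnts else mx
  out[cnts == 0L] <- NA_real_
  if (min_valid_frac > 0)
    out[cnts / factor^2 < min_valid_frac] <- NA_real_
  raster_grid(out, grid$res * factor, grid$origin)
}

#' Read / write rasters as ESRI ASCII grids
#'
#' The plain-text ESRI ASCII grid format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows north to south). `NA` cells
#' are written as the nodata sentinel and restored to `NA` on read.
#'
#' @param path file path (conventionally `.asc`).
#' @param grid a [raster_grid()] (for `write_raster`).
#' @param nodata sentinel written for `NA` cells.
#' @return `read_raster` returns a [raster_grid()]; `write_raster` returns
#'   `path` invisibly.
#' @export
read_raster <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) stop("truncated ASCII grid: ", path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed ASCII grid header line: ", lines[i])
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header missing: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"),
               what = double(), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("truncated ASCII grid: expected %d values, found %d",
                 nr * nc, length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  origin <- c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize)
  raster_grid(m, hdr$cellsize, origin)
}

#' @rdname read_raster
#' @export
write_raster <- function(grid, path, nodata = -9999) {
  if (!inherits(grid, "raster_grid")) stop("`grid` must be a raster_grid")
  v <- grid$values
  v[is.na(v)] <- nodata
  nr <- nrow(v); nc <- ncol(v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2] - nr * grid$res),
    sprintf("cellsize %.10g", grid$res),
    sprintf("NODATA_value %g", nodata)), con)
  writeLines(apply(v, 1, function(r) paste(format(r, digits = 17,
                                                  scientific = FALSE,
                                                  trim = TRUE),
                                           collapse = " ")), con)
  invisible(path)
}
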