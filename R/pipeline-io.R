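#' Run configuration
#'
#' Full parameterization of an end-to-end pipeline run: the scene, the
#' filtering thresholds and the model options. Round-trips losslessly
#' through YAML; unknown keys are rejected rather than silently ignored.
#'
#' @param scene named list of [scene_config()] overrides (must include
#'   `seed` or it defaults to 1).
#' @param filters named list of [filter_control()] arguments.
#' @param model named list: `sizes`, `reps`, `seed`, `method`, plus
#'   `tch_set`, `tpi_set`, `d_grid` for the prediction curves.
#' @return object of class `run_config`.
#' @export
run_config <- function(scene = list(), filters = list(), model = list()) {
  model_defaults <- list(sizes = c(3000, 4000, 5000), reps = 24, seed = 1,
                         method = "nls", tch_set = c(5, 20, 35),
                         tpi_set = c(-8.2, 9.0),
                         d_grid = seq(0, 1000, by = 10))
  fc_args <- formals(filter_control)
  unknown <- setdiff(names(filters), names(fc_args))
  if (length(unknown)) stop("unknown filter option(s): ",
                            paste(unknown, collapse = ", "))
  model <- merge_config(model_defaults, model)
  seed <- if (!is.null(scene$seed)) scene$seed else 1L
  scene$seed <- NULL
  cfg <- list(scene = do.call(scene_config,
                              c(list(seed = seed), scene)),
              filters = do.call(filter_control, filters),
              model = model)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg a [run_config()] (for writing).
#' @return `read_run_config` returns a [run_config()]; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), c("scene", "filters", "model"))
  if (length(unknown)) stop("unknown configuration block(s): ",
                            paste(unknown, collapse = ", "))
  run_config(scene = raw$scene %||% list(),
             filters = raw$filters %||% list(),
             model = raw$model %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- list(scene = unclass(cfg$scene), filters = unclass(cfg$filters),
              model = cfg$model)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Load a deposited or exported pixel dataset
#'
#' Reads a CSV of per-pixel values into the analysis pixel table. The column
#' map translates the file's column names to the internal schema; any field
#' whose mapped column is missing raises an error naming it. Either
#' `delta_tch` or both `tch_2014` and `tch_2016` must be mappable. Optional
#' fields (`twi`, `density_2014`, `cover`, `excluded_by`) default to
#' `NA`/"forest"/"".
#'
#' @param path CSV path.
#' @param column_map named character vector, internal name -> file column
#'   (defaults to identity for the internal schema).
#' @param quiet suppress the summary message.
#' @return a pixel table tibble (schema of [assemble_pixel_table()]).
#' @export
load_pixel_dataset <- function(path, column_map = NULL, quiet = FALSE) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cmap <- c(x = "x", y = "y", tch_2014 = "tch_2014", tch_2016 = "tch_2016",
            delta_tch = "delta_tch", tpi = "tpi", twi = "twi",
            d_edge = "d_edge", density_2014 = "density_2014",
            cover = "cover", excluded_by = "excluded_by")
  if (!is.null(column_map)) cmap[names(column_map)] <- unlist(column_map)
  pick <- function(nm) if (cmap[[nm]] %in% names(raw)) raw[[cmap[[nm]]]] else
    NULL
  need <- function(nm) {
    v <- pick(nm)
    if (is.null(v)) stop("required column `", nm, "` (mapped to `",
                         cmap[[nm]], "`) is missing from ", path)
    v
  }
  delta <- pick("delta_tch")
  t14 <- pick("tch_2014"); t16 <- pick("tch_2016")
  if (is.null(delta)) {
    if (is.null(t14) || is.null(t16))
      stop("need either `delta_tch` or both `tch_2014` and `tch_2016`",
           " columns in ", path)
    delta <- t16 - t14
  } else if (!is.null(t14) && is.null(t16)) t16 <- t14 + delta
  n <- length(delta)
  tab <- tibble::tibble(
    x = as.numeric(need("x")), y = as.numeric(need("y")),
    tch_2014 = if (is.null(t14)) rep(NA_real_, n) else as.numeric(t14),
    tch_2016 = if (is.null(t16)) rep(NA_real_, n) else as.numeric(t16),
    delta_tch = as.numeric(delta),
    tpi = as.numeric(need("tpi")),
    twi = if (is.null(pick("twi"))) rep(NA_real_, n) else
      as.numeric(pick("twi")),
    d_edge = as.numeric(need("d_edge")),
    density_2014 = if (is.null(pick("density_2014"))) rep(NA_real_, n) else
      as.numeric(pick("density_2014")),
    cover = if (is.null(pick("cover"))) rep("forest", n) else
      as.character(pick("cover")),
    excluded_by = if (is.null(pick("excluded_by"))) rep("", n) else {
      eb <- as.character(pick("excluded_by")); eb[is.na(eb)] <- ""; eb
    })
  if (!quiet)
    message(sprintf(
      "loaded %d pixels: delta TCH [%.2f, %.2f] m (mean %.3f), D_edge mean %.0f m",
      nrow(tab), min(tab$delta_tch, na.rm = TRUE),
      max(tab$delta_tch, na.rm = TRUE), mean(tab$delta_tch, na.rm = TRUE),
      mean(tab$d_edge, na.rm = TRUE)))
  tab
}

#' Write a pixel table to CSV
#'
#' @param table pixel table.
#' @param path output CSV.
#' @return `path` invisibly.
#' @export
write_pixel_table <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Export a synthetic scene to plain-text files
#'
#' Rasters as ESRI ASCII grids, censuses and climate as CSV, plus a YAML
#' manifest listing the members and the generating seed.
#'
#' @param scene a [generate_scene()] result.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "landscape_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  members <- list()
  for (nm in c("dtm", "cover", "tpi", "twi", "d_edge", "tch_2014",
               "tch_2016", "delta", "truth", "density")) {
    f <- file.path(dir, paste0(nm, ".asc"))
    g <- scene[[nm]]
    if (nm == "d_edge") {  # Inf distances are representable only as nodata
      g <- raster_grid(ifelse(is.finite(g$values), g$values, NA_real_),
                       g$res, g$origin)
    }
    write_raster(g, f)
    members[[nm]] <- basename(f)
  }
  if (!is.null(scene$plots)) {
    readr::write_csv(scene$plots, file.path(dir, "plot_census.csv"),
                     progress = FALSE)
    members$plots <- "plot_census.csv"
  }
  if (!is.null(scene$climate)) {
    readr::write_csv(scene$climate, file.path(dir, "climate.csv"),
                     progress = FALSE)
    members$climate <- "climate.csv"
  }
  manifest <- file.path(dir, "manifest.yml")
  yaml::write_yaml(list(seed = scene$config$seed, members = members),
                   manifest)
  invisible(manifest)
}

#' Run the full pipeline on a synthetic scene
#'
#' Scene generation, terrain metrics, pixel-table assembly (density-biased
#' first-survey heights), the filtering ledger, the subset ensemble of
#' asymptotic-model fits and the prediction curves, summarized in a
#' plain-text report that is byte-identical across reruns of the same
#' configuration.
#'
#' @param config a [run_config()].
#' @param report_path optional file to write the report lines to.
#' @return list with `scene`, `table`, `audit`, `ensemble`, `curves`,
#'   `recovery` (fitted vs generating coefficients) and `report` (character
#'   vector).
#' @export
run_pipeline <- function(config, report_path = NULL) {
  stopifnot(inherits(config, "run_config"))
  scene <- generate_scene(config$scene, include_aux = FALSE)
  tab <- assemble_pixel_table(scene$tch_2014_biased, scene$tch_2016,
                              scene$tpi, scene$twi, scene$d_edge,
                              scene$density, scene$cover30)
  led <- apply_filter_ledger(tab, config$filters)
  n_rows <- nrow(analysis_rows(led$table))
  sizes <- config$model$sizes[config$model$sizes < n_rows]
  if (!length(sizes))
    stop("pipeline stage `ensemble`: analysis table (", n_rows,
         " rows) smaller than every requested subset size")
  ens <- subset_ensemble(led$table, sizes = sizes,
                         reps = config$model$reps,
                         seed = config$model$seed,
                         method = config$model$method)
  curves <- prediction_curves(ens, tch_set = config$model$tch_set,
                              tpi_set = config$model$tpi_set,
                              d_grid = config$model$d_grid)
  gm <- config$scene$generating_model
  truth <- c(beta0 = gm$beta0, beta_tpi = gm$beta_tpi, beta_tch = gm$beta_tch,
             b = gm$edge_amp, c = gm$edge_rate)
  top <- ens[[length(ens)]]
  recovery <- tibble::tibble(parameter = names(truth),
                             generating = unname(truth),
                             median_fit = unname(top$median[names(truth)]),
                             cv_pct = unname(top$cv_pct[names(truth)]))
  report <- c(
    "canopy height change pipeline report",
    sprintf("scene seed: %d; analysis cells: %d; analysis rows: %d",
            config$scene$seed, length(scene$delta$values), n_rows),
    "",
    "filter ledger:",
    sprintf("  %-16s removed %6d, remaining %6d", led$audit$rule,
            led$audit$removed, led$audit$remaining),
    "",
    sprintf("ensemble: %d reps at sizes %s (%s, subset seed %d)",
            config$model$reps, paste(sizes, collapse = "/"),
            config$model$method, config$model$seed),
    "recovered coefficients (median of largest subset size) vs generating:",
    sprintf("  %-10s generating %+.5f, median %+.5f, CV %5.1f%%",
            recovery$parameter, recovery$generating, recovery$median_fit,
            recovery$cv_pct),
    "",
    sprintf("prediction curves: %d scenarios x %d distances",
            length(config$model$tch_set) * length(config$model$tpi_set),
            length(config$model$d_grid)))
  if (!is.null(report_path)) writeLines(report, report_path)
  list(scene = scene, table = led$table, audit = led$audit, ensemble = ens,
       curves = curves, recovery = recovery, report = report)
}

#' Check the deposited study datasets against the published summaries
#'
#' Optional verification against the archived pixel dataset (repeated canopy
#' height, TPI, distance from oil palm) and the archived plot microclimate
#' series, which must be downloaded separately. Recomputes the published
#' headline numbers: pixel count, mean distance to the edge, maximum TPI,
#' and the event-month temperature and VPD anomalies relative to the
#' 2013-2014 baseline.
#'
#' @param pixel_csv path to the deposited pixel CSV (optional).
#' @param climate_csv path to a CSV of plot T/RH series with columns
#'   mappable to `date`, `t_c`, `rh_pct`, `plot_id` (optional).
#' @param pixel_map,climate_map column maps (internal -> file column).
#' @param event_month,baseline_years anomaly definition.
#' @return tibble of (quantity, value); quantities whose input is absent are
#'   omitted. Errors if neither input is supplied.
#' @export
verify_deposited <- function(pixel_csv = NULL, climate_csv = NULL,
                             pixel_map = NULL, climate_map = NULL,
                             event_month = "2016-03-01",
                             baseline_years = c(2013, 2014)) {
  if (is.null(pixel_csv) && is.null(climate_csv))
    stop("supply `pixel_csv` and/or `climate_csv`: the deposited datasets ",
         "are not bundled and must be downloaded separately")
  rows <- list()
  if (!is.null(pixel_csv)) {
    if (!file.exists(pixel_csv)) stop("pixel dataset not found: ", pixel_csv)
    tab <- load_pixel_dataset(pixel_csv, column_map = pixel_map,
                              quiet = TRUE)
    tab <- analysis_rows(tab)
    rows$pixel_count <- nrow(tab)
    rows$mean_d_edge_m <- mean(tab$d_edge, na.rm = TRUE)
    rows$max_tpi <- max(tab$tpi, na.rm = TRUE)
  }
  if (!is.null(climate_csv)) {
    if (!file.exists(climate_csv)) stop("climate dataset not found: ",
                                        climate_csv)
    raw <- readr::read_csv(climate_csv, show_col_types = FALSE,
                           progress = FALSE)
    cmap <- c(date = "date", t_c = "t_c", rh_pct = "rh_pct",
              plot_id = "plot_id")
    if (!is.null(climate_map)) cmap[names(climate_map)] <-
        unlist(climate_map)
    missing <- cmap[!cmap %in% names(raw)]
    missing <- missing[names(missing) != "plot_id"]
    if (length(missing))
      stop("climate column(s) missing: ", paste(missing, collapse = ", "))
    ser <- tibble::tibble(date = raw[[cmap[["date"]]]],
                          t_c = as.numeric(raw[[cmap[["t_c"]]]]),
                          rh_pct = as.numeric(raw[[cmap[["rh_pct"]]]]))
    if (cmap[["plot_id"]] %in% names(raw))
      ser$plot_id <- raw[[cmap[["plot_id"]]]]
    an <- enso_anomaly(monthly_means(ser), event_month, baseline_years)
    rows$anomaly_t_c <- an$dT_C
    rows$anomaly_vpd_pct <- an$dVPD_pct
  }
  tibble::tibble(quantity = names(rows), value = unname(unlist(rows)))
}
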