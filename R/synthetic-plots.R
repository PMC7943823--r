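#' Generate synthetic field-plot censuses
#'
#' Emulates a network of 25 x 25 m permanent plots censused five times
#' (January 2013, December 2013, November 2014, December 2015, February
#' 2017). All stems have DBH >= 10 cm; height and crown area follow power-law
#' allometries with lognormal tree-level noise that persists across censuses;
#' diameter growth is Gaussian per year; mortality is Bernoulli per year
#' (dead trees stay in later censuses with `alive = FALSE` and frozen DBH);
#' recruits enter with new tree ids.
#'
#' @param cfg a [scene_config()]; see the `plots` block.
#' @param census_dates Date vector of census dates (default: the five study
#'   censuses).
#' @return tibble with columns `plot_id`, `census_date`, `tree_id`, `dbh_cm`,
#'   `height_m`, `crown_area_m2`, `alive`.
#' @export
generate_plot_inventory <- function(cfg,
    census_dates = as.Date(c("2013-01-15", "2013-12-15", "2014-11-15",
                             "2015-12-15", "2017-02-15"))) {
  cfg <- validate_scene_config(cfg)
  p <- cfg$plots
  if (length(census_dates) < 2) stop("need at least two census dates")
  census_dates <- sort(as.Date(census_dates))
  yrs <- as.numeric(diff(census_dates)) / 365.25
  out <- with_sub_seed(cfg$seed, "plots", {
    rows <- vector("list", p$n_plots)
    for (pl in seq_len(p$n_plots)) {
      n0 <- max(1L, stats::rpois(1, p$stems_per_plot_mean))
      dbh <- 10 + stats::rgamma(n0, shape = 1.2, scale = 12)
      eps_h <- stats::rnorm(n0, 0, p$allom_sdlog)
      eps_c <- stats::rnorm(n0, 0, p$allom_sdlog)
      id <- sprintf("P%02d_T%04d", pl, seq_len(n0))
      alive <- rep(TRUE, n0)
      next_id <- n0 + 1L
      per_census <- vector("list", length(census_dates))
      for (ci in seq_along(census_dates)) {
        if (ci > 1) {
          dt <- yrs[ci - 1]
          inc <- stats::rnorm(length(dbh), p$dbh_growth_mean_cm_yr * dt,
                              p$dbh_growth_sd_cm_yr * sqrt(dt))
          dbh <- ifelse(alive, pmax(10, dbh + inc), dbh)
          p_die <- 1 - (1 - p$mortality_rate_per_yr)^dt
          died <- alive & stats::runif(length(dbh)) < p_die
          alive[died] <- FALSE
          n_rec <- stats::rpois(1, n0 * p$recruitment_rate_per_yr * dt)
          if (n_rec > 0) {
            dbh <- c(dbh, 10 + stats::rgamma(n_rec, shape = 1.1, scale = 1.5))
            eps_h <- c(eps_h, stats::rnorm(n_rec, 0, p$allom_sdlog))
            eps_c <- c(eps_c, stats::rnorm(n_rec, 0, p$allom_sdlog))
            id <- c(id, sprintf("P%02d_T%04d", pl,
                                seq(next_id, length.out = n_rec)))
            alive <- c(alive, rep(TRUE, n_rec))
            next_id <- next_id + n_rec
          }
        }
        per_census[[ci]] <- tibble::tibble(
          plot_id = sprintf("P%02d", pl),
          census_date = census_dates[ci],
          tree_id = id,
          dbh_cm = dbh,
          height_m = p$allom_h[["a"]] * dbh^p$allom_h[["b"]] * exp(eps_h),
          crown_area_m2 = p$allom_ca[["a"]] * dbh^p$allom_ca[["b"]] *
            exp(eps_c),
          alive = alive)
      }
      rows[[pl]] <- dplyr::bind_rows(per_census)
    }
    dplyr::bind_rows(rows)
  })
  out
}

#' Generate a daily microclimate series
#'
#' Daily temperature, relative humidity and precipitation for an aseasonal
#' tropical site: Gaussian day-to-day variation about the baselines, gamma
#' precipitation, and additive ENSO anomalies (temperature up, humidity and
#' precipitation down) applied inside the configured event window. The series
#' represents the mean across the plot network, hence its small day-to-day
#' standard deviation. RH is clamped to [0, 100].
#'
#' @param cfg a [scene_config()]; see the `climate` block.
#' @return tibble with columns `date`, `t_c`, `rh_pct`, `precip_mm`.
#' @export
generate_microclimate <- function(cfg) {
  cfg <- validate_scene_config(cfg)
  cl <- cfg$climate
  dates <- seq(as.Date(cl$start), as.Date(cl$end), by = "day")
  if (length(dates) < 1) stop("empty climate span")
  ew <- as.Date(cl$event_window)
  in_event <- dates >= ew[1] & dates <= ew[2]
  with_sub_seed(cfg$seed, "climate", {
    n <- length(dates)
    t_c <- cl$baseline_t_c + cl$anomaly_t_c * in_event +
      stats::rnorm(n, 0, cl$sd_t_c)
    rh <- cl$baseline_rh_pct + cl$anomaly_rh_pct * in_event +
      stats::rnorm(n, 0, cl$sd_rh_pct)
    rh <- pmin(100, pmax(0, rh))
    scale0 <- cl$precip_mean_mm_day / cl$precip_shape
    pr <- stats::rgamma(n, shape = cl$precip_shape,
                        scale = scale0 * ifelse(in_event,
                                                cl$precip_anomaly_factor, 1))
    tibble::tibble(date = dates, t_c = t_c, rh_pct = rh, precip_mm = pr)
  })
}
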