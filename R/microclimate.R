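#' Saturation vapour pressure (Bolton)
#'
#' `e_s = 6.112 * exp(17.67 * T / (T + 243.5))` hPa, valid for
#' `T > -243.5` degC.
#'
#' @param t_c air temperature (degC).
#' @return saturation vapour pressure (hPa).
#' @export
saturation_vapour_pressure <- function(t_c) {
  if (any(t_c <= -243.5, na.rm = TRUE))
    stop("temperature must exceed -243.5 degC")
  6.112 * exp(17.67 * t_c / (t_c + 243.5))
}

#' Vapour pressure deficit
#'
#' `VPD = (100 - RH)/100 * e_s(T)`: the gap between how much moisture the
#' air could hold at saturation and how much it holds.
#'
#' @param t_c air temperature (degC).
#' @param rh_pct relative humidity (%) in [0, 100].
#' @return VPD (hPa).
#' @export
vpd <- function(t_c, rh_pct) {
  if (any(rh_pct < 0 | rh_pct > 100, na.rm = TRUE))
    stop("relative humidity must be within [0, 100]")
  (100 - rh_pct) / 100 * saturation_vapour_pressure(t_c)
}

#' Monthly means of temperature and VPD
#'
#' VPD is computed per record and then averaged (the mean of per-record VPD
#' generally differs from the VPD of mean T and RH because the formula is
#' nonlinear). Grouping is per plot when a `plot_id` column is present.
#' Empty months are simply absent from the output.
#'
#' @param series tibble with `date`, `t_c`, `rh_pct` and optionally
#'   `plot_id`.
#' @return tibble with `plot_id` (if given), `month` (first-of-month Date),
#'   `t_mean`, `vpd_mean`, `n`.
#' @export
monthly_means <- function(series) {
  s <- series
  s$vpd_rec <- vpd(s$t_c, s$rh_pct)
  s$month <- as.Date(format(as.Date(s$date), "%Y-%m-01"))
  grp <- if ("plot_id" %in% names(s)) c("plot_id", "month") else "month"
  out <- dplyr::summarise(dplyr::group_by(s, dplyr::across(dplyr::all_of(grp))),
                          t_mean = mean(.data$t_c),
                          vpd_mean = mean(.data$vpd_rec),
                          n = dplyr::n(), .groups = "drop")
  dplyr::arrange(out, dplyr::across(dplyr::all_of(grp)))
}

#' Trailing running precipitation
#'
#' Sum of precipitation over the trailing `window` days (the day itself and
#' the `window - 1` before it). The first `window - 1` days are undefined.
#' Calendar gaps in the series invalidate every window they touch unless
#' `max_gap_days` tolerance is raised (missing days then contribute zero).
#'
#' @param daily tibble with `date` and `precip_mm`.
#' @param window window length in days (default 30).
#' @param max_gap_days number of missing days tolerated per window.
#' @return tibble `date`, `precip_mm`, `running_mm`.
#' @export
running_precip <- function(daily, window = 30, max_gap_days = 0) {
  d <- daily[order(as.Date(daily$date)), , drop = FALSE]
  dates <- as.Date(d$date)
  if (anyDuplicated(dates)) stop("duplicate dates in daily series")
  full <- seq(min(dates), max(dates), by = "day")
  p <- rep(NA_real_, length(full))
  p[match(dates, full)] <- d$precip_mm
  present <- !is.na(p)
  p0 <- ifelse(present, p, 0)
  cs <- cumsum(p0); cn <- cumsum(present)
  run <- rep(NA_real_, length(full))
  i <- window:length(full)
  tot <- cs[i] - c(0, cs)[i - window + 1]
  nmiss <- window - (cn[i] - c(0, cn)[i - window + 1])
  run[i] <- ifelse(nmiss <= max_gap_days, tot, NA_real_)
  tibble::tibble(date = full, precip_mm = p, running_mm = run)
}

#' ENSO anomalies of temperature and VPD
#'
#' Compares one event month against the mean over all months of the baseline
#' (non-event) years: `dT = T(event) - mean(T, baseline)` and the VPD
#' anomaly expressed in percent of the baseline VPD.
#'
#' @param monthly a [monthly_means()] table (plot means are averaged per
#'   month first when several plots are present).
#' @param event_month the event month, anything `as.Date` accepts for the
#'   first of that month (e.g. `"2016-03-01"`).
#' @param baseline_years integer vector of calendar years (e.g.
#'   `c(2013, 2014)`).
#' @return list with `dT_C` and `dVPD_pct`.
#' @export
enso_anomaly <- function(monthly, event_month, baseline_years) {
  m <- monthly
  if ("plot_id" %in% names(m))
    m <- dplyr::summarise(dplyr::group_by(m, .data$month),
                          t_mean = mean(.data$t_mean),
                          vpd_mean = mean(.data$vpd_mean), .groups = "drop")
  ev <- as.Date(event_month)
  ev <- as.Date(format(ev, "%Y-%m-01"))
  row <- m[m$month == ev, , drop = FALSE]
  if (nrow(row) != 1) stop("event month absent from the monthly table")
  yrs <- as.integer(format(m$month, "%Y"))
  base <- m[yrs %in% baseline_years, , drop = FALSE]
  if (nrow(base) == 0) stop("no baseline months in the monthly table")
  base_vpd <- mean(base$vpd_mean)
  list(dT_C = row$t_mean - mean(base$t_mean),
       dVPD_pct = 100 * (row$vpd_mean - base_vpd) / base_vpd)
}
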