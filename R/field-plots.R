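#' Standard deviation of the DBH measurement error
#'
#' The census protocol's error model: `s = 0.9036 + 0.006214 * DBH` (cm),
#' increasing with stem size.
#'
#' @param dbh_cm diameter at breast height (cm), non-negative.
#' @return measurement-error sd (cm).
#' @export
dbh_error_sd <- function(dbh_cm) {
  if (any(dbh_cm < 0, na.rm = TRUE)) stop("DBH must be non-negative")
  0.9036 + 0.006214 * dbh_cm
}

#' Clean implausible diameter growth between two censuses
#'
#' Flags stems whose annualized DBH growth is at least `growth_max_cm_yr`
#' (default 5 cm/yr) or whose total shrinkage is at least `shrink_mult`
#' (default 12) times the DBH measurement-error sd at the first census.
#' Flagged stems are assigned the first-census DBH plus the interval times
#' the mean annual increment of unflagged live stems of the same size class
#' (per-plot DBH quartile bins); a size class with no unflagged stems falls
#' back to the whole-plot mean, then to the network mean.
#'
#' @param census_t0,census_t1 census tibbles (same schema as
#'   [generate_plot_inventory()]) for the two dates, matched on
#'   `plot_id` + `tree_id`.
#' @param interval_yr census interval in years (> 0).
#' @param growth_max_cm_yr annual growth flag threshold (cm/yr).
#' @param shrink_mult shrinkage flag threshold, in multiples of
#'   [dbh_error_sd()] at the initial DBH.
#' @return `census_t1` with corrected `dbh_cm` plus logical column `flagged`
#'   and column `dbh_cm_raw`.
#' @export
clean_growth <- function(census_t0, census_t1, interval_yr,
                         growth_max_cm_yr = 5, shrink_mult = 12) {
  if (interval_yr <= 0) stop("interval must be positive")
  key0 <- paste(census_t0$plot_id, census_t0$tree_id)
  key1 <- paste(census_t1$plot_id, census_t1$tree_id)
  m <- match(key1, key0)
  dbh0 <- census_t0$dbh_cm[m]
  alive_both <- !is.na(m) & census_t1$alive & census_t0$alive[m]
  growth_yr <- (census_t1$dbh_cm - dbh0) / interval_yr
  shrink <- dbh0 - census_t1$dbh_cm
  flagged <- alive_both &
    (growth_yr >= growth_max_cm_yr |
       shrink >= shrink_mult * dbh_error_sd(dbh0))
  flagged[is.na(flagged)] <- FALSE

  out <- census_t1
  out$dbh_cm_raw <- out$dbh_cm
  out$flagged <- flagged
  if (!any(flagged)) return(out)

  # mean annual increments of unflagged live stems, per plot x DBH quartile
  ref <- tibble::tibble(plot_id = census_t1$plot_id, dbh0 = dbh0,
                        inc = growth_yr)[alive_both & !flagged, ]
  network_mean <- mean(ref$inc)
  for (pl in unique(out$plot_id[flagged])) {
    in_plot <- ref$plot_id == pl
    qs <- if (sum(in_plot) >= 4)
      stats::quantile(ref$dbh0[in_plot], c(0.25, 0.5, 0.75), names = FALSE)
    else numeric(0)
    bin_of <- function(d) findInterval(d, qs) + 1L
    plot_mean <- if (any(in_plot)) mean(ref$inc[in_plot]) else NA_real_
    fl <- which(flagged & out$plot_id == pl)
    for (i in fl) {
      b <- bin_of(dbh0[i])
      same <- in_plot & bin_of(ref$dbh0) == b
      rate <- if (any(same)) mean(ref$inc[same])
      else if (!is.na(plot_mean)) plot_mean
      else network_mean
      if (!is.finite(rate)) rate <- 0
      out$dbh_cm[i] <- dbh0[i] + interval_yr * rate
    }
  }
  out
}

#' Fit height and crown-area allometries
#'
#' Log-log least-squares fits `ln H = a_H + b_H ln DBH` and
#' `ln CA = a_C + b_C ln DBH`, with Duan's smearing factor
#' (`mean(exp(residuals))`) stored for bias-corrected back-transformation.
#'
#' @param trees tibble with positive `dbh_cm` and measured `height_m` and/or
#'   `crown_area_m2` (at least 10 stems per fitted relationship).
#' @return object of class `allometry_fit` with components `height` and
#'   `crown_area`, each holding `coef` (intercept, slope on the log scale),
#'   `sigma` and `smearing`.
#' @export
fit_allometry <- function(trees) {
  fit_one <- function(y, what) {
    ok <- !is.na(y) & !is.na(trees$dbh_cm)
    if (sum(ok) < 10) stop("need >= 10 trees with measured ", what)
    if (any(trees$dbh_cm[ok] <= 0) || any(y[ok] <= 0))
      stop("DBH and ", what, " must be positive for the log-log fit")
    fit <- stats::lm(log(y[ok]) ~ log(trees$dbh_cm[ok]))
    res <- stats::residuals(fit)
    list(coef = unname(stats::coef(fit)),
         sigma = sqrt(mean(res^2)),
         smearing = mean(exp(res)))
  }
  structure(list(height = fit_one(trees$height_m, "height"),
                 crown_area = fit_one(trees$crown_area_m2, "crown area")),
            class = "allometry_fit")
}

#' Predict height and crown area from DBH
#'
#' @param fit an [fit_allometry()] result.
#' @param dbh_cm diameters (cm).
#' @return tibble with `height_m` and `crown_area_m2` (smearing-corrected).
#' @export
predict_allometry <- function(fit, dbh_cm) {
  pr <- function(f) exp(f$coef[1] + f$coef[2] * log(dbh_cm)) * f$smearing
  tibble::tibble(height_m = pr(fit$height),
                 crown_area_m2 = pr(fit$crown_area))
}

#' Crown-area-weighted canopy height of a plot census
#'
#' The field analogue of LiDAR top-of-canopy height: stems are ranked by
#' crown area (ties broken by larger DBH, then tree id) and overstory stems
#' selected from the top of the list until their cumulative crown area first
#' reaches the plot area (625 m2; the stem crossing the threshold is
#' included whole); the statistic is the crown-area-weighted mean height of
#' the selected stems.
#'
#' @param census one plot-census tibble with `height_m`, `crown_area_m2`
#'   (live stems are used; `alive` column honoured when present).
#' @param plot_area_m2 selection threshold (default 625).
#' @return field-estimated TCH (m).
#' @export
crown_weighted_tch <- function(census, plot_area_m2 = 625) {
  tr <- census
  if ("alive" %in% names(tr)) tr <- tr[tr$alive, , drop = FALSE]
  tr <- tr[!is.na(tr$crown_area_m2) & !is.na(tr$height_m), , drop = FALSE]
  if (nrow(tr) == 0 || sum(tr$crown_area_m2) == 0)
    stop("total crown area is zero")
  ord <- order(-tr$crown_area_m2, -tr$dbh_cm, tr$tree_id)
  tr <- tr[ord, , drop = FALSE]
  cum <- cumsum(tr$crown_area_m2)
  n_sel <- if (any(cum >= plot_area_m2)) which(cum >= plot_area_m2)[1] else
    nrow(tr)
  sel <- tr[seq_len(n_sel), , drop = FALSE]
  sum(sel$crown_area_m2 * sel$height_m) / sum(sel$crown_area_m2)
}

#' Basal-area mortality and growth between two censuses
#'
#' Decomposes plot dynamics into the basal area of stems that died over the
#' interval (summed at their initial size) and the basal-area increment of
#' surviving stems. Recruits (ids absent at the first census) are reported
#' separately and excluded from both terms. Basal area per stem is
#' `pi * (dbh_cm / 200)^2` m2.
#'
#' @param census_t0,census_t1 matched census tibbles.
#' @return list with `ba_mortality_m2`, `ba_growth_m2`, `ba_recruit_m2`,
#'   and stem counts `n_died`, `n_survived`, `n_recruits`.
#' @export
basal_area_dynamics <- function(census_t0, census_t1) {
  ba <- function(d) pi * (d / 200)^2
  key0 <- paste(census_t0$plot_id, census_t0$tree_id)
  key1 <- paste(census_t1$plot_id, census_t1$tree_id)
  m <- match(key0, key1)
  a0 <- census_t0$alive
  a1 <- ifelse(is.na(m), FALSE, census_t1$alive[m])
  if (any(!a0 & a1, na.rm = TRUE))
    stop("stem dead at the first census is alive at the second: data error")
  died <- a0 & !a1
  surv <- a0 & a1
  recruits <- !(key1 %in% key0) & census_t1$alive
  list(ba_mortality_m2 = sum(ba(census_t0$dbh_cm[died])),
       ba_growth_m2 = sum(ba(census_t1$dbh_cm[m[surv]]) -
                            ba(census_t0$dbh_cm[surv])),
       ba_recruit_m2 = sum(ba(census_t1$dbh_cm[recruits])),
       n_died = sum(died), n_survived = sum(surv),
       n_recruits = sum(recruits))
}

#' Plot-level regressions linking LiDAR and field change
#'
#' Two ordinary least-squares fits across plots: (a) LiDAR height change
#' against field-estimated height change and plant-area-index change;
#' (b) field-estimated height change against basal-area mortality and
#' basal-area growth. Returns coefficients, R2 and per-predictor marginal
#' F tests (Type II).
#'
#' @param plots tibble with one row per plot and columns
#'   `delta_tch_lidar`, `delta_tch_field`, `delta_pai`, `ba_mortality`,
#'   `ba_growth` (a fit is skipped if its columns are absent).
#' @return list of fits; each has `coefficients`, `r_squared`, `f_tests`
#'   (tibble of predictor, F, p) and the underlying `lm` object.
#' @export
plot_regressions <- function(plots) {
  fit_lm <- function(formula, data) {
    vars <- all.vars(formula)
    data <- data[stats::complete.cases(data[, vars]), , drop = FALSE]
    if (nrow(data) < length(vars) + 1)
      stop("need at least ", length(vars) + 1, " complete plots for ",
           deparse(formula))
    fit <- stats::lm(formula, data = data)
    if (any(is.na(stats::coef(fit)))) stop("rank-deficient design in ",
                                           deparse(formula))
    dr <- stats::drop1(fit, test = "F")
    list(coefficients = stats::coef(fit),
         r_squared = summary(fit)$r.squared,
         f_tests = tibble::tibble(predictor = rownames(dr)[-1],
                                  F = dr$`F value`[-1],
                                  p = dr$`Pr(>F)`[-1]),
         n = nrow(data), lm = fit)
  }
  out <- list()
  if (all(c("delta_tch_lidar", "delta_tch_field", "delta_pai") %in%
          names(plots)))
    out$lidar_vs_field <- fit_lm(
      delta_tch_lidar ~ delta_tch_field + delta_pai, plots)
  if (all(c("delta_tch_field", "ba_mortality", "ba_growth") %in%
          names(plots)))
    out$field_vs_ba <- fit_lm(
      delta_tch_field ~ ba_mortality + ba_growth, plots)
  if (!length(out)) stop("no recognisable response/predictor columns")
  out
}

#' Plant area index from canopy openness
#'
#' Beer-Lambert gap-fraction inversion: `PAI = -ln(openness) / k` with
#' extinction coefficient `k` (default 0.5, spherical leaf-angle
#' distribution).
#'
#' @param openness gap fraction in (0, 1].
#' @param k extinction coefficient (> 0).
#' @return PAI (m2 per m2).
#' @export
pai_from_openness <- function(openness, k = 0.5) {
  if (k <= 0) stop("extinction coefficient must be positive")
  if (any(openness <= 0, na.rm = TRUE))
    stop("openness must be positive (saturated canopy)")
  if (any(openness > 1, na.rm = TRUE)) stop("openness cannot exceed 1")
  -log(openness) / k
}
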