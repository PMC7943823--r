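test_that("the DBH measurement-error model follows its printed form", {
  expect_equal(dbh_error_sd(0), 0.9036)
  expect_equal(dbh_error_sd(100), 1.5250)
  d <- seq(10, 150, by = 5)
  expect_true(all(diff(dbh_error_sd(d)) > 0))
  expect_error(dbh_error_sd(-1), "non-negative")
})

test_that("clean_growth flags extreme growth and shrinkage correctly", {
  t0 <- tibble::tibble(plot_id = "P1", census_date = as.Date("2014-01-01"),
                       tree_id = sprintf("T%02d", 1:20),
                       dbh_cm = c(20, seq(12, 50, length.out = 19)),
                       alive = TRUE)
  t1 <- t0
  t1$census_date <- as.Date("2015-01-01")
  t1$dbh_cm <- t0$dbh_cm + 1            # ordinary 1 cm/yr growth
  t1$dbh_cm[2] <- t0$dbh_cm[2] + 5.5    # >= 5 cm/yr: flagged
  t1$dbh_cm[1] <- 20 - 13               # shrink 13 > 12 * s(20) = 12.34
  t1$dbh_cm[3] <- t0$dbh_cm[3] - 5      # shrink 5 < 12 * s: kept
  out <- clean_growth(t0, t1, interval_yr = 1)
  expect_true(out$flagged[1])
  expect_true(out$flagged[2])
  expect_false(out$flagged[3])
  # unflagged stems never change
  expect_identical(out$dbh_cm[!out$flagged], t1$dbh_cm[!out$flagged])
  # flagged stems get a plausible replacement near the unflagged mean rate
  rates <- (out$dbh_cm[out$flagged] - t0$dbh_cm[out$flagged])
  expect_true(all(rates > -2 & rates < 2))
})

test_that("flag count is monotone non-increasing in the growth threshold", {
  set.seed(40)
  t0 <- tibble::tibble(plot_id = "P1", census_date = as.Date("2014-01-01"),
                       tree_id = sprintf("T%03d", 1:200),
                       dbh_cm = runif(200, 10, 80), alive = TRUE)
  t1 <- t0
  t1$dbh_cm <- t0$dbh_cm + rnorm(200, 1, 2.5)
  counts <- vapply(c(2, 4, 6, 8), function(th)
    sum(clean_growth(t0, t1, 1, growth_max_cm_yr = th)$flagged), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("allometry fits are exact on noiseless power laws", {
  set.seed(41)
  dbh <- runif(60, 10, 90)
  trees <- tibble::tibble(dbh_cm = dbh, height_m = 3 * dbh^0.6,
                          crown_area_m2 = 0.5 * dbh^1.2)
  fit <- fit_allometry(trees)
  expect_equal(fit$height$coef[2], 0.6, tolerance = 1e-9)
  expect_equal(fit$height$coef[1], log(3), tolerance = 1e-9)
  expect_equal(fit$crown_area$coef[2], 1.2, tolerance = 1e-9)
  expect_equal(fit$height$smearing, 1, tolerance = 1e-12)
  pred <- predict_allometry(fit, 50)
  expect_equal(pred$height_m, 3 * 50^0.6, tolerance = 1e-9)
})

test_that("allometry slope is recovered under lognormal noise", {
  set.seed(42)
  dbh <- runif(1000, 10, 90)
  trees <- tibble::tibble(dbh_cm = dbh,
                          height_m = 3 * dbh^0.6 * exp(rnorm(1000, 0, 0.2)),
                          crown_area_m2 = 0.5 * dbh^1.2 *
                            exp(rnorm(1000, 0, 0.2)))
  fit <- fit_allometry(trees)
  expect_lt(abs(fit$height$coef[2] - 0.6), 0.02)
  expect_gt(fit$height$smearing, 1)   # Jensen: mean(exp(res)) > 1
  expect_error(fit_allometry(trees[1:5, ]), ">= 10")
})

test_that("crown-area-weighted height follows the overstory selection rule", {
  two <- tibble::tibble(tree_id = c("a", "b"), dbh_cm = c(60, 50),
                        height_m = c(30, 20), crown_area_m2 = c(400, 300))
  expect_equal(crown_weighted_tch(two), (400 * 30 + 300 * 20) / 700,
               tolerance = 1e-12)
  expect_equal(round(crown_weighted_tch(two), 3), 25.714)

  first_only <- tibble::tibble(tree_id = c("a", "b"), dbh_cm = c(90, 40),
                               height_m = c(28, 15),
                               crown_area_m2 = c(700, 300))
  expect_equal(crown_weighted_tch(first_only), 28.0)

  same_h <- tibble::tibble(tree_id = sprintf("t%d", 1:8), dbh_cm = 30,
                           height_m = 17, crown_area_m2 = runif(8, 50, 200))
  expect_equal(crown_weighted_tch(same_h), 17)
  expect_error(crown_weighted_tch(
    tibble::tibble(tree_id = "a", dbh_cm = 20, height_m = 10,
                   crown_area_m2 = 0)), "zero")
})

test_that("crown-weighted height is invariant to input order and scaling", {
  set.seed(43)
  census <- tibble::tibble(tree_id = sprintf("t%02d", 1:40),
                           dbh_cm = runif(40, 10, 80),
                           height_m = runif(40, 5, 40),
                           crown_area_m2 = runif(40, 10, 120))
  a <- crown_weighted_tch(census)
  b <- crown_weighted_tch(census[sample(40), ])
  expect_equal(a, b, tolerance = 1e-12)
  scaled <- census
  scaled$crown_area_m2 <- census$crown_area_m2 * 3
  expect_equal(crown_weighted_tch(scaled, plot_area_m2 = 625 * 3), a,
               tolerance = 1e-12)
})

test_that("basal-area dynamics decompose mortality, growth and recruits", {
  t0 <- tibble::tibble(plot_id = "P1", tree_id = c("a", "b", "c"),
                       dbh_cm = c(40, 20, 30), alive = TRUE)
  t1 <- tibble::tibble(plot_id = "P1", tree_id = c("a", "b", "c", "d"),
                       dbh_cm = c(40, 22, 30, 12),
                       alive = c(FALSE, TRUE, TRUE, TRUE))
  out <- basal_area_dynamics(t0, t1)
  expect_equal(out$ba_mortality_m2, pi * 0.04, tolerance = 1e-12)
  expect_equal(round(out$ba_mortality_m2, 5), 0.12566)
  expect_equal(out$ba_growth_m2, pi * (0.11^2 - 0.10^2), tolerance = 1e-12)
  expect_equal(round(out$ba_growth_m2, 6), 0.006597)
  expect_equal(out$n_recruits, 1)
  expect_equal(out$ba_recruit_m2, pi * 0.06^2, tolerance = 1e-12)

  none <- basal_area_dynamics(t0, within(t0, alive <- TRUE))
  expect_equal(none$ba_mortality_m2, 0)
  expect_equal(none$ba_growth_m2, 0)

  bad0 <- t0; bad0$alive[1] <- FALSE     # dead at t0 ...
  bad1 <- t1; bad1$alive[1] <- TRUE      # ... but alive again at t1
  expect_error(basal_area_dynamics(bad0, bad1), "data error")
})

test_that("plot regressions recover exact coefficients and reject noise", {
  set.seed(44)
  n <- 38
  plots <- tibble::tibble(ba_mortality = runif(n, 0, 0.3),
                          ba_growth = runif(n, 0, 0.1))
  plots$delta_tch_field <- 0.1 - 2 * plots$ba_mortality +
    5 * plots$ba_growth
  # a noiseless response makes lm's F machinery warn about the perfect fit
  fit <- suppressWarnings(plot_regressions(plots)$field_vs_ba)
  expect_equal(unname(fit$coefficients), c(0.1, -2, 5), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # permuting the response destroys the fit
  perm <- plots
  perm$delta_tch_field <- sample(perm$delta_tch_field)
  expect_lt(plot_regressions(perm)$field_vs_ba$r_squared, 0.2)
})

test_that("calibrated plot noise reproduces the strong BA-model fit", {
  # noise sd chosen analytically so the expected variance explained is 77%
  r2s <- vapply(1:10, function(s) {
    set.seed(400 + s)
    n <- 38
    ba_m <- runif(n, 0, 0.3); ba_g <- runif(n, 0, 0.12)
    signal <- -2.5 * ba_m + 6 * ba_g
    noise_sd <- sqrt(var(signal) * (1 / 0.77 - 1))
    df <- tibble::tibble(ba_mortality = ba_m, ba_growth = ba_g,
                         delta_tch_field = 0.1 + signal +
                           rnorm(n, 0, noise_sd))
    plot_regressions(df)$field_vs_ba$r_squared
  }, numeric(1))
  expect_equal(mean(r2s), 0.77, tolerance = 0.08)
})

test_that("field height change tracks net basal-area change across plots", {
  cfg <- small_cfg(seed = 45, plots = list(n_plots = 200,
                                           stems_per_plot_mean = 40,
                                           mortality_rate_per_yr = 0.04))
  inv <- generate_plot_inventory(cfg)
  dates <- sort(unique(inv$census_date))
  t0 <- inv[inv$census_date == dates[1], ]
  t1 <- inv[inv$census_date == dates[length(dates)], ]
  stats <- lapply(split(seq_len(nrow(t0)), t0$plot_id), function(i) {
    pl <- t0$plot_id[i[1]]
    a <- t0[i, ]; b <- t1[t1$plot_id == pl, ]
    dyn <- basal_area_dynamics(a, b)
    c(d_tch = crown_weighted_tch(b) - crown_weighted_tch(a),
      net = dyn$ba_growth_m2 - dyn$ba_mortality_m2)
  })
  m <- do.call(rbind, stats)
  expect_gt(cor(m[, "d_tch"], m[, "net"]), 0)
})

test_that("PAI inversion follows Beer-Lambert and is monotone", {
  expect_equal(pai_from_openness(1), 0)
  expect_equal(pai_from_openness(0.5, k = 0.5), 1.3863, tolerance = 1e-4)
  op <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(pai_from_openness(op)) < 0))
  expect_error(pai_from_openness(0), "positive")
  expect_error(pai_from_openness(0.5, k = 0), "positive")
})
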