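test_that("the candidate set contains the required model forms", {
  cands <- build_candidates()
  expect_gte(length(cands), 4)
  asym <- cands$asymptotic
  expect_true(asym$edge)
  expect_setequal(asym$par_names, c("beta0", "beta_tpi", "beta_tch",
                                    "b", "c"))
  inter <- cands$asymptotic_interactions
  expect_true(all(c("beta_tch_tpi", "beta_tch_d") %in% inter$par_names))
  expect_false(cands$linear$edge)
  # parameter counts are nested-comparable
  ks <- vapply(cands, function(s) length(s$par_names), numeric(1))
  expect_true(all(diff(sort(ks)) >= 0))
  expect_error(model_spec("x", c("tpi", "tpi")), "duplicated")
  expect_error(model_spec("x", "bogus"), "unknown")
})

test_that("noiseless data are recovered exactly with near-zero residual", {
  tab <- simulate_eq2_rows(600, sd = 0, seed = 60)
  fit <- fit_nls(build_candidates()$asymptotic, tab)
  expect_equal(unname(fit$coefficients), unname(eq1_params),
               tolerance = 1e-6)
  expect_lt(fit$rss, 1e-8)
  # accepted optimizer steps never increase the objective
  expect_true(all(diff(fit$sse_path) <= 1e-12))
})

test_that("fit_nls agrees with the stats::nls oracle on noisy data", {
  tab <- simulate_eq2_rows(2000, sd = 0.9, seed = 61)
  fit <- fit_nls(build_candidates()$asymptotic, tab)
  oracle <- stats::nls(
    delta_tch ~ b0 + b1 * tpi + b2 * tch_2014 - b * exp(-cc * d_edge),
    data = tab,
    start = list(b0 = 0.5, b1 = 0, b2 = 0, b = 1, cc = 0.01))
  oc <- coef(oracle)[c("b0", "b1", "b2", "b", "cc")]
  expect_equal(unname(fit$coefficients), unname(oc), tolerance = 1e-5)
  expect_equal(fit$rss, sum(resid(oracle)^2), tolerance = 1e-8)
})

test_that("noisy synthetic data recover the generating coefficients", {
  tab <- simulate_eq2_rows(5000, sd = 0.9, seed = 62)
  fit <- fit_nls(build_candidates()$asymptotic, tab)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$coefficients - eq1_params) < 3 * se))
})

test_that("an absent edge effect yields an amplitude near zero", {
  p0 <- eq1_params; p0[["b"]] <- 0
  tab <- simulate_eq2_rows(3000, sd = 0.9, seed = 63, params = p0)
  fit <- fit_nls(build_candidates()$asymptotic, tab)
  expect_lt(abs(fit$coefficients[["b"]]),
            2 * sqrt(fit$vcov["b", "b"]) + 1e-6)
})

test_that("spatial GLS reduces to NLS in the uncorrelated limit", {
  tab <- simulate_eq2_rows(400, sd = 0.9, seed = 64)
  nls_fit <- fit_nls(build_candidates()$asymptotic, tab)
  gls_fit <- fit_gls_spatial(build_candidates()$asymptotic, tab,
                             rho = 1e-6)
  expect_equal(unname(gls_fit$coefficients), unname(nls_fit$coefficients),
               tolerance = 1e-4)
})

test_that("spatial GLS agrees with the nlme::gnls oracle", {
  skip_if_not_installed("nlme")
  set.seed(65)
  n <- 300
  xy <- cbind(runif(n, 0, 3000), runif(n, 0, 3000))
  dm <- as.matrix(dist(xy))
  Sigma <- 0.81 * exp(-dm / 120)
  noise <- drop(rnorm(n) %*% chol(Sigma))
  tpi <- rnorm(n, 0, 5); tch <- runif(n, 0, 64); d <- rexp(n, 1 / 400)
  mu <- 0.6576 - 0.02142 * tpi - 0.0172 * tch - 0.8553 * exp(-0.0049 * d)
  tab <- tibble::tibble(x = xy[, 1], y = xy[, 2], tch_2014 = tch,
                        tch_2016 = tch + mu + noise,
                        delta_tch = mu + noise, tpi = tpi, twi = NA,
                        d_edge = d, density_2014 = 13, cover = "forest",
                        excluded_by = "")
  fit <- fit_gls_spatial(build_candidates()$asymptotic, tab)
  oracle <- nlme::gnls(
    delta_tch ~ b0 + b1 * tpi + b2 * tch_2014 - b * exp(-cc * d_edge),
    data = as.data.frame(tab),
    params = list(b0 + b1 + b2 + b + cc ~ 1),
    start = c(b0 = 0.6, b1 = 0, b2 = -0.01, b = 0.8, cc = 0.005),
    correlation = nlme::corExp(form = ~ x + y))
  oc <- coef(oracle)
  expect_equal(unname(fit$coefficients), unname(oc), tolerance = 0.02)
  expect_equal(fit$rho,
               as.numeric(nlme::intervals(oracle)$corStruct[, "est."]),
               tolerance = 0.15)
  expect_equal(fit$logLik, as.numeric(stats::logLik(oracle)),
               tolerance = 0.01)
})

test_that("GLS standard errors exceed NLS ones under positive correlation", {
  set.seed(66)
  n <- 400
  xy <- cbind(runif(n, 0, 2000), runif(n, 0, 2000))
  dm <- as.matrix(dist(xy))
  Sigma <- 0.81 * exp(-dm / 90)
  noise <- drop(rnorm(n) %*% chol(Sigma))
  tpi <- rnorm(n, 0, 5); tch <- runif(n, 0, 64); d <- rexp(n, 1 / 400)
  mu <- 0.6576 - 0.02142 * tpi - 0.0172 * tch - 0.8553 * exp(-0.0049 * d)
  tab <- tibble::tibble(x = xy[, 1], y = xy[, 2], tch_2014 = tch,
                        tch_2016 = tch + mu + noise,
                        delta_tch = mu + noise, tpi = tpi, twi = NA,
                        d_edge = d, density_2014 = 13, cover = "forest",
                        excluded_by = "")
  nf <- fit_nls(build_candidates()$asymptotic, tab)
  gf <- fit_gls_spatial(build_candidates()$asymptotic, tab)
  expect_gte(sqrt(gf$vcov["beta0", "beta0"]),
             sqrt(nf$vcov["beta0", "beta0"]))
})

test_that("the correlogram range is recovered within a factor of two", {
  ranges <- vapply(1:10, function(s) {
    set.seed(700 + s)
    n <- 300
    xy <- cbind(runif(n, 0, 3000), runif(n, 0, 3000))
    dm <- as.matrix(dist(xy))
    noise <- drop(rnorm(n) %*% chol(0.81 * exp(-dm / 90)))
    tpi <- rnorm(n, 0, 5); tch <- runif(n, 0, 64); d <- rexp(n, 1 / 400)
    mu <- 0.6576 - 0.02142 * tpi - 0.0172 * tch -
      0.8553 * exp(-0.0049 * d)
    tab <- tibble::tibble(x = xy[, 1], y = xy[, 2], tch_2014 = tch,
                          tch_2016 = tch + mu + noise,
                          delta_tch = mu + noise, tpi = tpi, twi = NA,
                          d_edge = d, density_2014 = 13, cover = "forest",
                          excluded_by = "")
    fit_gls_spatial(build_candidates()$asymptotic, tab)$rho
  }, numeric(1))
  med <- median(ranges)
  expect_gt(med, 45)
  expect_lt(med, 180)
})

test_that("AIC selection prefers parsimony and checks row identity", {
  expect_equal(aic_value(3, -100), 206)
  expect_equal(aic_value(5, -100), 210)
  expect_equal(aic_value(5, -7849.5), 15709)
  tab <- simulate_eq2_rows(900, sd = 0.9, seed = 67)
  cands <- build_candidates()
  fits <- lapply(cands, fit_nls, table = tab)
  best <- select_by_aic(fits)
  expect_true(best$spec$edge)
  at <- attr(best, "aic_table")
  expect_equal(at$aic[1], min(at$aic))
  other <- fit_nls(cands$asymptotic, simulate_eq2_rows(900, seed = 99))
  expect_error(select_by_aic(list(fits$linear, other)), "differing")
})

test_that("subset ensembles are seed-reproducible with nested sizes", {
  tab <- simulate_eq2_rows(3000, sd = 0.9, seed = 68)
  e1 <- subset_ensemble(tab, sizes = c(500, 800), reps = 6, seed = 5)
  e2 <- subset_ensemble(tab, sizes = c(500, 800), reps = 6, seed = 5)
  expect_identical(e1[["500"]]$params, e2[["500"]]$params)
  e3 <- subset_ensemble(tab, sizes = c(500, 800), reps = 6, seed = 6)
  expect_false(identical(e1[["500"]]$params, e3[["500"]]$params))
  expect_error(subset_ensemble(tab, sizes = 5000, reps = 2, seed = 1),
               "exceeds")
  # medians land near a full-table fit
  full <- fit_nls(build_candidates()$asymptotic, tab)
  se <- sqrt(diag(full$vcov))
  expect_true(all(abs(e1[["800"]]$median - full$coefficients) <
                    4 * se * sqrt(3000 / 800)))
})

test_that("corrected intervals scale half-widths by sqrt(n/N)", {
  tab <- simulate_eq2_rows(1200, sd = 0.9, seed = 69)
  fit <- fit_nls(build_candidates()$asymptotic, tab)
  ci <- corrected_intervals(fit, n = 5000, N = 36655)
  expect_equal(unique(ci$scale_factor), sqrt(5000 / 36655))
  expect_equal(unique(ci$scale_factor), 0.3694, tolerance = 1e-3)
  hw_model <- (ci$upper_model - ci$lower_model) / 2
  hw_corr <- (ci$upper_corrected - ci$lower_corrected) / 2
  expect_equal(hw_corr, hw_model * sqrt(5000 / 36655), tolerance = 1e-12)
  ident <- corrected_intervals(fit, n = 10, N = 10)
  expect_equal(ident$lower_model, ident$lower_corrected)
  expect_error(corrected_intervals(fit, 10, 5), "n <= N")
})

test_that("predictions follow the closed form and are monotone in distance", {
  expect_equal(predict_delta_tch(eq1_params, 0, 0, 1e9), 0.6576,
               tolerance = 1e-9)
  expect_equal(predict_delta_tch(eq1_params, 0, 0, 0), 0.6576 - 0.8553,
               tolerance = 1e-9)
  expect_equal(round(predict_delta_tch(eq1_params, 0, 0, 0), 4), -0.1977)
  d <- seq(0, 2000, by = 10)
  pr <- predict_delta_tch(eq1_params, 0, 5, d)
  expect_true(all(diff(pr) > 0))
  expect_error(predict_delta_tch(eq1_params, 0, 0, -5), "non-negative")
})

test_that("edge penetration distance matches its closed form", {
  expect_equal(edge_penetration_distance(eq1_params, 0, 0),
               -log(0.6576 / 0.8553) / 0.0049, tolerance = 1e-9)
  expect_equal(round(edge_penetration_distance(eq1_params, 0, 0), 1), 53.6)
  expect_equal(round(edge_penetration_distance(eq1_params, 0, 5), 1), 82.2)
  # the crossing distance is where the prediction changes sign
  d0 <- edge_penetration_distance(eq1_params, 0, 5)
  expect_equal(predict_delta_tch(eq1_params, 0, 5, d0), 0,
               tolerance = 1e-9)
  # plateau at or below zero: no crossing
  expect_true(is.na(edge_penetration_distance(eq1_params, 0, 45)))
  bad <- eq1_params; bad[["c"]] <- -0.1
  expect_error(edge_penetration_distance(bad, 0, 0), "positive")
})

test_that("prediction curves cover the scenario grid with sane ordering", {
  tab <- simulate_eq2_rows(2500, sd = 0.9, seed = 70)
  ens <- subset_ensemble(tab, sizes = c(600, 1000), reps = 8, seed = 3)
  cur <- prediction_curves(ens, d_grid = seq(0, 500, by = 50))
  expect_equal(nrow(cur), 3 * 2 * 11)
  expect_equal(length(unique(paste(cur$tch_2014, cur$tpi))), 6)
  # valley curves above hilltop curves for the negative TPI coefficient
  for (h in c(5, 20, 35)) {
    v <- cur[cur$tch_2014 == h & cur$tpi == -8.2, ]
    r <- cur[cur$tch_2014 == h & cur$tpi == 9.0, ]
    expect_true(all(v$pred > r$pred))
  }
  # monotone increasing in distance, and CI bands enclose the predictions
  one <- cur[cur$tch_2014 == 5 & cur$tpi == 9.0, ]
  expect_true(all(diff(one$pred) > 0))
  expect_true(all(one$lower <= one$pred & one$pred <= one$upper))
  expect_error(prediction_curves(ens, d_grid = numeric(0)), "empty")
})
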