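test_that("ground interpolation is exact on a plane and ignores canopy", {
  set.seed(20)
  n <- 200
  pts <- data.frame(x = runif(n, 0, 20), y = runif(n, 0, 20))
  pts$z <- 2 * pts$x + 3 * pts$y
  pts$is_ground <- TRUE
  canopy <- data.frame(x = runif(50, 0, 20), y = runif(50, 0, 20),
                       z = 999, is_ground = FALSE)
  dtm <- grid_points_to_dtm(rbind(pts, canopy), res = 1)
  cc <- cell_centres(dtm)
  want <- 2 * cc$x + 3 * cc$y
  inside <- !is.na(dtm$values)
  expect_gt(sum(inside), 200)   # most of the hull is covered
  expect_lt(max(abs(dtm$values[inside] - want[inside])), 1e-6)
})

test_that("interpolation matches the barycentric oracle on one triangle", {
  pts <- data.frame(x = c(0, 10, 0), y = c(0, 0, 10), z = c(0, 10, 10),
                    is_ground = TRUE)
  dtm <- grid_points_to_dtm(pts, res = 1, origin = c(0, 10),
                            nrow = 10, ncol = 10)
  # cell centre (2.5, 3.5): barycentric weights on z = (0, 10, 10)
  v <- dtm$values[7, 3]    # row 7 -> y = 3.5, col 3 -> x = 2.5
  expect_equal(v, 10 * (2.5 / 10) + 10 * (3.5 / 10), tolerance = 1e-9)
  expect_error(grid_points_to_dtm(data.frame(x = 1:2, y = 1:2, z = 0,
                                             is_ground = TRUE)),
               "3 ground")
  collinear <- data.frame(x = 1:5, y = 1:5, z = 0, is_ground = TRUE)
  expect_error(grid_points_to_dtm(collinear), "collinear")
})

test_that("CHM takes per-cell maxima of heights above ground, clamped", {
  dtm <- raster_grid(matrix(100, 10, 10), 1, origin = c(0, 10))
  pts <- data.frame(
    x = c(1.2, 1.4, 3.1, 5.5), y = c(9.1, 9.3, 9.5, 0.5),
    z = c(110, 118, 125, 95),   # heights 10, 18, 25, -5
    is_ground = FALSE)
  chm <- build_chm(pts, dtm, res = 2)
  expect_equal(chm$values[1, 1], 18)   # max of 10 and 18 in one 2 m cell
  expect_equal(chm$values[1, 2], 25)
  expect_equal(chm$values[5, 3], 0)    # below-ground return clamped
  expect_true(is.na(chm$values[3, 3])) # empty cell
})

test_that("TCH block means and the validity rule follow the 50% contract", {
  # 225 sub-cells at 2 m: 112 at 10 m and 113 at 20 m
  v <- c(rep(10, 112), rep(20, 113))
  chm <- raster_grid(matrix(v, 15, 15), 2, origin = c(0, 30))
  tch <- tch_from_chm(chm)
  expect_equal(tch$values[1, 1], (112 * 10 + 113 * 20) / 225,
               tolerance = 1e-12)
  expect_equal(round(tch$values[1, 1], 3), 15.022)

  const <- raster_grid(matrix(7.5, 15, 15), 2, origin = c(0, 30))
  expect_equal(tch_from_chm(const)$values[1, 1], 7.5)

  v2 <- rep(NA_real_, 225); v2[1:90] <- 10    # 60% nodata
  part <- raster_grid(matrix(v2, 15, 15), 2, origin = c(0, 30))
  expect_true(is.na(tch_from_chm(part)$values[1, 1]))
  expect_error(tch_from_chm(raster_grid(matrix(1, 10, 10), 7)), "divide")
})

test_that("pixel table assembly computes deltas and rejects misalignment", {
  tab <- toy_pixel_table(nr = 4, nc = 4, delta = matrix(0, 4, 4))
  expect_true(all(tab$delta_tch == 0))
  tab2 <- toy_pixel_table(nr = 4, nc = 4, delta = matrix(2.5, 4, 4))
  expect_true(all(abs(tab2$delta_tch - 2.5) < 1e-12))
  a <- rg(matrix(1, 4, 4)); b <- rg(matrix(1, 4, 4), origin = c(15, 120))
  expect_error(assemble_pixel_table(a, b, a, a, a, a, a), "aligned")
})

test_that("filter ledger matches the exhaustive per-cell oracle", {
  # toy 10x10 scene: an oil palm block, a clearcut patch whose 200 m buffer
  # reaches neighbours, one road column, and scattered low-density cells
  cov <- matrix(cover_classes[["forest"]], 10, 10)
  cov[1:4, 1:2] <- cover_classes[["oil_palm"]]
  cov[7:8, 7:8] <- cover_classes[["clearcut"]]
  cov[, 5] <- cover_classes[["road"]]
  dens <- matrix(13, 10, 10)
  set.seed(30)
  dens[sample(100, 6)] <- 5
  tab <- toy_pixel_table(nr = 10, nc = 10, cover = cov, density = dens)
  ctl <- filter_control()
  led <- apply_filter_ledger(tab, ctl)
  oracle <- brute_filter_flags(tab, ctl)
  got <- strsplit(led$table$excluded_by, ",")
  got[lengths(got) == 0] <- list(character(0))
  expect_identical(lapply(got, sort), lapply(oracle, sort))
  expect_equal(nrow(analysis_rows(led$table)), sum(lengths(oracle) == 0))
  # audit bookkeeping: remaining is non-increasing and consistent
  expect_true(all(diff(led$audit$remaining) <= 0))
  expect_equal(led$audit$remaining[nrow(led$audit)],
               nrow(analysis_rows(led$table)))
})

test_that("1% trimming removes exactly the extreme tail ranks", {
  set.seed(31)
  tab <- toy_pixel_table(nr = 25, nc = 40)   # 1000 forest survivors
  led <- apply_filter_ledger(tab, filter_control(clearcut_buffer_m = 0,
                                                 road_buffer_m = NA,
                                                 density_threshold = 0))
  expect_equal(sum(grepl("trimmed", led$table$excluded_by)), 20)
  d <- tab$delta_tch
  cut_lo <- sort(d)[10]; cut_hi <- sort(d, decreasing = TRUE)[10]
  trimmed <- led$table$excluded_by == "trimmed"
  expect_true(all(d[trimmed] <= cut_lo | d[trimmed] >= cut_hi))
})

test_that("the ledger is idempotent and disabled filters are no-ops", {
  tab <- toy_pixel_table(nr = 8, nc = 8)
  off <- filter_control(exclude_non_forest = FALSE, clearcut_buffer_m = 0,
                        road_buffer_m = NA, density_threshold = 0,
                        trim_fraction = 0)
  led0 <- apply_filter_ledger(tab, off)
  expect_identical(led0$table, tab)
  expect_true(all(led0$audit$removed == 0))

  cov <- matrix(cover_classes[["forest"]], 8, 8)
  cov[1:2, 1:2] <- cover_classes[["oil_palm"]]
  tab2 <- toy_pixel_table(nr = 8, nc = 8, cover = cov)
  ctl <- filter_control()
  once <- apply_filter_ledger(tab2, ctl)
  twice <- apply_filter_ledger(once$table, ctl)
  expect_identical(twice$table, once$table)
  expect_true(all(twice$audit$removed == 0))
  expect_error(apply_filter_ledger(tab2[0, ], ctl), "empty")
})

test_that("density bias inflates apparent change in the excluded pixels", {
  cfg <- small_cfg(seed = 32)
  tab <- simulate_pixel_table(cfg, use_biased_tch = TRUE)
  led <- apply_filter_ledger(tab, filter_control(clearcut_buffer_m = 0,
                                                 road_buffer_m = NA))
  low <- grepl("low_density", led$table$excluded_by)
  kept <- led$table$excluded_by == ""
  expect_gt(sum(low), 50)
  expect_gt(mean(led$table$delta_tch[low]),
            mean(led$table$delta_tch[kept]))
})
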