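test_that("observation assembly preserves rows and flags conflicts", {
  objs <- data.frame(id = 1:100, x_um = runif(100), y_um = runif(100),
                     area_um2 = rnorm(100, 50))
  set <- assemble_observations(objs, "area_um2")
  expect_equal(nrow(set), 100L)
  expect_equal(attr(set, "provenance"), "per_cell")
  # records with a missing metric are excluded with a count
  objs$area_um2[c(3, 7)] <- NA
  expect_message(set2 <- assemble_observations(objs, "area_um2"), "2 record")
  expect_equal(nrow(set2), 98L)
  # mixed provenance errors
  tiles <- data.frame(tile = 1:60, x_um = runif(60), y_um = runif(60),
                      mean_intensity = runif(60))
  expect_error(assemble_observations(list(objs, tiles), "x_um"),
               "provenance conflict")
  expect_error(assemble_observations(objs[1:5, ], "area_um2"), "at least 10")
})

test_that("hold-out split is exact, exhaustive and seeded", {
  set <- data.frame(x_um = runif(1000), y_um = runif(1000), z = rnorm(1000))
  sp <- split_holdout(set, 0.10, seed = 3)
  expect_equal(nrow(sp$test), 100L)
  expect_equal(nrow(sp$train), 900L)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:1000)
  expect_identical(sp$test_idx, split_holdout(set, 0.10, seed = 3)$test_idx)
  # minimum test size of 1
  sp10 <- split_holdout(set[1:10, ], 0.10, seed = 1)
  expect_equal(nrow(sp10$test), 1L)
  expect_error(split_holdout(set, 1.5), "test_fraction")
})

test_that("degenerate all-identical labels yield a noise-only model with warning", {
  tr <- data.frame(x_um = runif(50), y_um = runif(50), z = rep(2, 50))
  expect_warning(h <- optimize_hyperparameters(tr, seed = 1), "identical")
  expect_lt(h$signal_var, 1e-6)
})

test_that("prediction grids honor the requested size and bounding box", {
  set.seed(5)
  tr <- data.frame(x_um = runif(60, 0, 100), y_um = runif(60, 0, 50),
                   z = rnorm(60))
  surf <- fit_surface(tr, list(length_scales = c(20, 20), signal_var = 1,
                               noise_var = 0.1, kernel = "se"))
  g <- predict_grid(surf, total_points = 5000)
  expect_equal(g$n_points, 5000L)
  expect_equal(length(g$x_um) * length(g$y_um), 5000L)
  # corners equal the observation bounding box exactly
  expect_equal(range(g$x_um), range(tr$x_um))
  expect_equal(range(g$y_um), range(tr$y_um))
  expect_true(all(g$z_sd >= 0))
  # void filling: all predictions finite and within the plausible label band
  expect_true(all(is.finite(g$z_mean)))
  expect_true(all(g$z_mean >= min(tr$z) - 3 * sqrt(1) &
                  g$z_mean <= max(tr$z) + 3 * sqrt(1)))
})

test_that("void regions are filled about as accurately as populated ones", {
  topo <- exponential_profile()
  mm <- response_model("axonal_growth", 5)
  sc <- make_scene(topo, mm, density_per_cm2 = 10000, void_fraction = 0.3,
                   seed = 21, height_um = 10000)
  obs <- scene_observations(sc)
  sp <- split_holdout(obs, 0.1, seed = 22)
  hyp <- optimize_hyperparameters(sp$train, n_iterations = 15, seed = 23,
                                  max_train = 400)
  surf <- fit_surface(sp$train, hyp, max_train = 400)
  g <- predict_grid(surf, total_points = 10000)
  xy <- expand.grid(x = g$x_um, y = g$y_um)
  truth <- response_value(mm, stats::approx(topo$position_um,
                                            topo$period_um, xout = xy$x,
                                            rule = 2)$y)
  v <- sc$void_regions
  inv <- rep(FALSE, nrow(xy))
  for (i in seq_len(nrow(v)))
    inv <- inv | (xy$x >= v$x0[i] & xy$x <= v$x1[i] &
                  xy$y >= v$y0[i] & xy$y <= v$y1[i])
  err <- as.vector(g$z_mean) - truth
  expect_gt(sum(inv), 0)
  expect_lt(sqrt(mean(err[inv]^2)), 2 * sqrt(mean(err[!inv]^2)))
})

test_that("hold-out error behaves at its limits", {
  set.seed(6)
  tr <- data.frame(x_um = runif(40), y_um = runif(40), z = NA)
  tr$z <- sin(6 * tr$x_um)
  surf <- fit_surface(tr, list(length_scales = c(0.3, 0.3), signal_var = 1,
                               noise_var = 1e-10, kernel = "se"))
  # test = training subset on a noise-free interpolating fit
  err <- holdout_error(surf, tr[1:10, ])
  expect_lt(err$rmse, 1e-5)
  expect_gt(err$r2, 0.999)
  # constant predictor against varying labels scores r2 <= 0
  trc <- tr; trc$z <- 1
  surfc <- fit_surface(trc, list(length_scales = c(0.3, 0.3), signal_var = 1,
                                 noise_var = 1e-6, kernel = "se"))
  test <- data.frame(x_um = runif(20), y_um = runif(20), z = rnorm(20))
  expect_lte(holdout_error(surfc, test)$r2, 1e-6)
})

test_that("size-curve marginalization respects calibration and structure", {
  topo <- exponential_profile()
  cal <- fit_size_calibration(topo)
  # a y-independent monotone surface produces a monotone curve
  tr <- data.frame(x_um = seq(0, 10000, length.out = 120),
                   y_um = rep(c(1000, 9000), 60))
  tr$z <- tr$x_um / 10000
  surf <- fit_surface(tr, list(length_scales = c(2000, 2000), signal_var = 1,
                               noise_var = 1e-8, kernel = "se"))
  g <- predict_grid(surf, total_points = 4900)
  cv <- marginalize_to_size_curve(g, cal, 8)
  expect_true(all(diff(cv$bin) > 0))
  # position increases as size decreases on this array
  expect_true(all(diff(cv$mean) < 0))
  # grid outside the calibrated range errors
  surf2 <- surf; surf2$bbox <- list(x = c(-4000, 9000), y = c(0, 9000))
  g2 <- predict_grid(surf2, total_points = 2500)
  expect_error(marginalize_to_size_curve(g2, cal, 8), "calibration range")
})
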