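test_that("background subtraction removes flat and ramped illumination", {
  # constant image -> all zeros
  expect_true(all(subtract_background(matrix(0.4, 80, 80), 10) == 0))
  # blob on flat background b: peak reduced by exactly b
  img <- matrix(0.2, 120, 120)
  img <- stamp_disk(img, 60, 60, 40, value = 0.9)
  out <- subtract_background(img, 15)
  expect_equal(max(out), 0.7, tolerance = 1e-9)
  # blob on a linear ramp: residual ramp amplitude < 10% of the original
  ramp <- matrix(rep(seq(0, 0.5, length.out = 120), 120), 120, 120)
  img2 <- stamp_disk(ramp, 60, 60, 40, value = 0.95)
  out2 <- subtract_background(img2, 15)
  corners <- out2[cbind(c(5, 115), c(5, 115))]
  expect_lt(abs(diff(corners)), 0.1 * 0.5)
  expect_error(subtract_background(matrix(0, 20, 20), 30), "smaller")
})

test_that("area filter retains exactly the in-range blobs", {
  img <- matrix(0, 200, 80)
  img <- stamp_disk(img, 40, 40, 5)     # below the 8 px bound
  img <- stamp_disk(img, 100, 40, 40)   # inside [8, 80]
  img <- stamp_disk(img, 160, 40, 120)  # above the 80 px bound
  obj <- detect_objects(img, threshold = 0.5)
  expect_equal(nrow(obj), 1L)
  expect_true(obj$area_px >= 8 && obj$area_px <= 80)
  # blank image: empty collection, not an error
  expect_equal(nrow(detect_objects(matrix(0, 50, 50))), 0L)
  # filter is exact on a busy random field
  set.seed(8)
  busy <- matrix(0, 300, 300)
  for (i in 1:30)
    busy <- stamp_disk(busy, runif(1, 15, 285), runif(1, 15, 285),
                       sample(3:130, 1))
  ob <- detect_objects(busy, threshold = 0.5)
  expect_true(all(ob$area_px >= 8 & ob$area_px <= 80))
})

test_that("rendered blobs round-trip through detection", {
  # single cell of known half-maximum footprint
  topo <- exponential_profile(length_um = 200, n_samples = 20)
  m <- response_model("adhesion", 20)
  sc <- make_scene(topo, m, density_per_cm2 = 0, void_fraction = 0, seed = 1,
                   height_um = 200)
  sc$cells <- data.frame(id = 1, x_um = 100, y_um = 100, z = 1, z_true = 1,
                         size_um = 5, area_um2 = 40 * 0.65^2,
                         eccentricity = 0.3, orientation_deg = 20)
  img <- render_fluorescence_image(sc, "actin", noise_scale = 0)
  # threshold at the blob's half maximum recovers the nominal footprint
  obj <- detect_objects(img, threshold = 0.05 + 0.45)
  expect_equal(nrow(obj), 1L)
  expect_lt(abs(obj$area_px - 40) / 40, 0.15)
  # empty scene renders pure background
  sc0 <- sc; sc0$cells <- sc$cells[0, ]
  img0 <- render_fluorescence_image(sc0, "actin", noise_scale = 0)
  expect_true(all(img0 == 0.05))
})

test_that("ten disjoint blobs are recovered with sub-pixel centroids", {
  img <- matrix(0, 400, 120)
  cx <- seq(30, 370, length.out = 10); cy <- rep(60, 10)
  for (i in 1:10) img <- stamp_disk(img, cx[i], cy[i], 20)
  obj <- detect_objects(img, threshold = 0.5)
  expect_equal(nrow(obj), 10L)
  px <- 0.65
  err <- sapply(seq_len(nrow(obj)), function(i)
    min(sqrt((obj$x_um[i] / px - (cx - 1))^2 +
             (obj$y_um[i] / px - (cy - 1))^2)))
  expect_lt(max(err), 1)
})

test_that("shape metrics match pixel-counting expectations", {
  disk <- matrix(0L, 60, 60)
  for (i in 1:60) for (j in 1:60)
    if ((i - 30)^2 + (j - 30)^2 <= 400) disk[i, j] <- 1L
  s <- measure_shape(disk)
  expect_gte(s$circularity, 0.9)
  sq <- matrix(0L, 50, 50); sq[11:40, 11:40] <- 1L
  s2 <- measure_shape(sq)
  # digital boundary-pixel perimeter sits a little above the continuous pi/4
  expect_gt(s2$circularity, 0.7)
  expect_lt(s2$circularity, 0.95)
  ln <- matrix(0L, 80, 20); ln[11:60, 10] <- 1L
  s3 <- measure_shape(ln)
  expect_lt(s3$circularity, 0.3)
  expect_gte(s3$major_axis_px / s3$minor_axis_px, 10)
  # single pixel: clipped circularity, defined polarization
  s4 <- measure_shape(matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3))
  expect_equal(s4$circularity, 1)
  expect_equal(s4$polarization, 0)
  expect_error(measure_shape(matrix(0, 4, 4)), "empty")
})

test_that("tile pixelization partitions the image exactly", {
  img <- matrix(0.3, 120, 60)
  tl <- pixelize_intensity(img, 48)
  expect_equal(nrow(tl), 48L)
  expect_true(all(abs(tl$mean_intensity - 0.3) < 1e-12))
  expect_equal(sum(tl$tile_w_px * tl$tile_h_px), 120 * 60)
  # left bright / right dark along x (first index): exact means
  img2 <- rbind(matrix(1, 60, 60), matrix(0, 60, 60))
  tl2 <- pixelize_intensity(img2, 48)
  expect_true(all(tl2$mean_intensity %in% c(0, 1)))
  expect_true(all(tl2$mean_intensity[tl2$x_um < 60 * 0.65] == 1))
  expect_true(all(tl2$mean_intensity[tl2$x_um > 60 * 0.65] == 0))
  expect_error(pixelize_intensity(img, 30), "48")
  expect_error(pixelize_intensity(img, 600), "576")
})

test_that("tile profile tracks the ground-truth differentiation response", {
  topo <- exponential_profile(length_um = 3000, n_samples = 200)
  m <- response_model("differentiation", 2, log_width = 1.0, noise_sd = 0.1)
  sc <- make_scene(topo, m, density_per_cm2 = 40000, void_fraction = 0,
                   seed = 6, height_um = 1000)
  img <- render_fluorescence_image(sc, "tuj1_map2", seed = 7)
  tl <- pixelize_intensity(subtract_background(img, 20), 48)
  prof <- stats::aggregate(mean_intensity ~ x_um, tl, mean)
  pred <- response_value(m, stats::approx(topo$position_um, topo$period_um,
                                          xout = prof$x_um, rule = 2)$y)
  expect_gte(stats::cor(prof$mean_intensity, pred), 0.8)
})

test_that("proliferation ratio is exact and scale invariant", {
  img <- matrix(0, 200, 80)
  for (i in 1:6) img <- stamp_disk(img, 20 + 30 * i, 40, 30, value = 0.8)
  obj <- detect_objects(img, threshold = 0.4)
  expect_equal(nrow(obj), 6L)
  r1 <- proliferation_ratio(img, img, obj)
  expect_true(all(abs(r1$prolif_ratio - 1) < 1e-12))
  r2 <- proliferation_ratio(2 * img, img, obj)
  expect_true(all(abs(r2$prolif_ratio - 2) < 1e-12))
  r5 <- proliferation_ratio(5 * 2 * img, 5 * img, obj)
  expect_equal(r5$prolif_ratio, r2$prolif_ratio, tolerance = 1e-12)
  # zero DAPI: object flagged and dropped
  dapi0 <- img; dapi0[] <- 0
  expect_message(r0 <- proliferation_ratio(img, dapi0, obj), "dropped")
  expect_equal(nrow(r0), 0L)
})
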