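test_that("scenes are bitwise reproducible under a fixed seed", {
  s1 <- fixture_scene(seed = 9, density = 3000, length_um = 3000,
                      height_um = 3000)
  s2 <- fixture_scene(seed = 9, density = 3000, length_um = 3000,
                      height_um = 3000)
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$void_regions, s2$void_regions)
  s3 <- fixture_scene(seed = 10, density = 3000, length_um = 3000,
                      height_um = 3000)
  expect_false(identical(s1$cells, s3$cells))
})

test_that("position sampling follows the requested density and voids", {
  topo <- exponential_profile()                  # 1 cm
  # zero density: empty
  p0 <- sample_cell_positions(topo, 0, 0, seed = 1, height_um = 10000)
  expect_equal(nrow(p0$positions), 0L)
  # Poisson concentration: 10,000 per cm^2 over 1 cm^2
  counts <- sapply(1:3, function(s)
    nrow(sample_cell_positions(topo, 10000, 0, seed = s,
                               height_um = 10000)$positions))
  expect_true(all(abs(counts - 10000) <= 3 * sqrt(10000)))
  # no cell centre inside any void rectangle (exact)
  ps <- sample_cell_positions(topo, 5000, 0.3, seed = 4, height_um = 10000)
  v <- ps$voids
  expect_gt(nrow(v), 0L)
  inside <- rep(FALSE, nrow(ps$positions))
  for (i in seq_len(nrow(v)))
    inside <- inside | (ps$positions$x_um >= v$x0[i] &
                        ps$positions$x_um <= v$x1[i] &
                        ps$positions$y_um >= v$y0[i] &
                        ps$positions$y_um <= v$y1[i])
  expect_false(any(inside))
  expect_error(sample_cell_positions(topo, 1000, 1), "void_fraction")
})

test_that("behavior values follow the peaked response model", {
  topo <- exponential_profile()
  m <- response_model("axonal_growth", 5, amplitude = 1, baseline = 0.2,
                      noise_sd = 0)
  cal <- fit_size_calibration(topo)
  x_peak <- feature_size_to_position(cal, 5)
  x_far <- feature_size_to_position(cal, 0.12)
  obs <- sample_behavior_values(
    data.frame(x_um = c(x_peak, x_far), y_um = c(1, 1)), topo, m, seed = 1)
  expect_equal(obs$z[1], 1.2, tolerance = 1e-3)       # baseline + amplitude
  expect_equal(obs$z[2], 0.2, tolerance = 1e-2)       # tail reverts to baseline
  # noise residual mean obeys the CLT bound over 10,000 draws
  m2 <- response_model("adhesion", 20, noise_sd = 0.15)
  pos <- data.frame(x_um = runif(10000, 0, 10000), y_um = runif(10000, 0, 100))
  obs2 <- sample_behavior_values(pos, topo, m2, seed = 2)
  expect_lt(abs(mean(obs2$z - obs2$z_true)), 3 * 0.15 / 100)
})

test_that("ground-truth peak sizes are stored on the scene", {
  sc <- fixture_scene(peak = 5, seed = 3, density = 2000,
                      length_um = 3000, height_um = 1000)
  expect_equal(sc$model$peak_size_um, 5)
  expect_true(all(c("z", "z_true", "size_um") %in% names(sc$cells)))
  # noiseless values agree with the response model at the stored sizes
  expect_equal(sc$cells$z_true,
               response_value(sc$model, sc$cells$size_um))
})

test_that("sub-seed fan-out is deterministic and tag-sensitive", {
  expect_identical(sub_seed(7, "a", "b"), sub_seed(7, "a", "b"))
  expect_false(sub_seed(7, "a") == sub_seed(7, "b"))
  expect_false(sub_seed(7, "a") == sub_seed(8, "a"))
  expect_true(sub_seed(2^30, "long", "tag", 123) < 2^31)
})
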