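test_that("grating equation reproduces the closed-form two-beam periods", {
  # symmetric 30 degrees from normal: period equals the wavelength
  expect_equal(grating_period(325, 30, 30), 0.325, tolerance = 1e-9)
  # counter-propagating grazing: the lambda/2 diffraction limit
  expect_equal(grating_period(325, 90, 90), 0.1625, tolerance = 1e-9)
  # co-propagating degenerate sum is clamped with a warning
  expect_warning(p <- grating_period(325, 30, -30), "clamped")
  expect_gt(p, 1e3)
})

test_that("duty-cycle closed form matches known cases and a numerical oracle", {
  expect_equal(fringe_duty_cycle(1, 0.5, 1), 0.5)
  expect_equal(fringe_duty_cycle(1, 0.5, 1.5), 0)
  expect_equal(fringe_duty_cycle(1, 0.5, 0.75), 2 / 3, tolerance = 1e-12)
  # tone flip
  expect_equal(fringe_duty_cycle(1, 0.5, 0.75, "positive"), 1 / 3,
               tolerance = 1e-12)
  # zero visibility: all-or-nothing with a warning
  expect_warning(d0 <- fringe_duty_cycle(1, 0, 0.5), "visibility")
  expect_equal(d0, 1)
  # against root-located threshold crossings, across random settings
  set.seed(42)
  for (i in 1:25) {
    m <- runif(1, 0.5, 2); v <- runif(1, 0.1, 1)
    t <- m + runif(1, -1.2, 1.2) * v
    expect_equal(fringe_duty_cycle(m, v, t), oracle_duty_cycle(m, v, t),
                 tolerance = 1e-9)
  }
})

test_that("flat-mirror (Lloyd) limit gives the specular angle and a constant period", {
  g <- interferometer_geometry(focal_length_mm = Inf)
  th <- trace_reflected_angle(g, c(0, 2500, 9000))
  expect_equal(th, rep(67, 3))
  p <- build_topography_profile(g, n_samples = 60)
  expect_equal(diff(range(p$period_um)), 0)
  expect_equal(p$period_um[1], 0.325 / (2 * cos(67 * pi / 180)),
               tolerance = 1e-9)
  expect_true(all(p$duty_cycle == 0.5))
})

test_that("traced reflected angle matches a brute-force sweep oracle and is continuous", {
  g <- interferometer_geometry()
  x_mid <- 5000
  ang <- trace_reflected_angle(g, x_mid)
  # recover the mirror-frame abscissa of the exposure origin from a probe at 0
  fan_edge_probe <- nanomap:::.exposure_frame(g)
  x_mm <- fan_edge_probe$x0_mm + fan_edge_probe$dir * x_mid / 1000
  expect_equal(ang, oracle_reflected_angle(67, 10, x_mm), tolerance = 0.02)
  # continuity
  th <- trace_reflected_angle(g, c(4000, 4000.5, 4001))
  expect_lt(max(abs(diff(th))), 0.01)
})

test_that("positions outside the illuminated branch raise an informative error", {
  g <- interferometer_geometry()
  expect_error(trace_reflected_angle(g, -500), "not illuminated")
  expect_error(trace_reflected_angle(g, 5e5), "not illuminated")
})

test_that("default gradient profile spans a wide, monotone, physical period range", {
  g <- interferometer_geometry()   # beta 67, f 10 mm
  p <- build_topography_profile(g)
  expect_gte(max(p$period_um) / min(p$period_um), 50)
  expect_true(all(p$period_um >= 0.325 / 2))
  # monotone period for the monotone reflected-angle sweep
  expect_true(all(diff(p$period_um) < 0) || all(diff(p$period_um) > 0))
  expect_equal(p$linewidth_um, p$duty_cycle * p$period_um)
  expect_true(all(p$duty_cycle >= 0 & p$duty_cycle <= 1))
})

test_that("degenerate two-sample profile still satisfies the invariants", {
  g <- interferometer_geometry()
  p <- build_topography_profile(g, n_samples = 2)
  expect_equal(nrow(p), 2L)
  expect_true(all(p$period_um >= 0.325 / 2))
  expect_equal(p$linewidth_um, p$duty_cycle * p$period_um)
})

test_that("steeper beam angles narrow the simulated period span", {
  spans <- sapply(c(62, 67, 72), function(b) {
    g <- interferometer_geometry(beam_angle_deg = b, substrate_length_mm = 15)
    p <- build_topography_profile(g, n_samples = 200)
    max(p$period_um) / min(p$period_um)
  })
  expect_true(all(diff(spans) < 0))
})

test_that("geometry constructor validates its invariants", {
  expect_error(interferometer_geometry(beam_angle_deg = 95))
  expect_error(interferometer_geometry(wavelength_nm = -1))
  expect_error(interferometer_geometry(focal_length_mm = 0))
})
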