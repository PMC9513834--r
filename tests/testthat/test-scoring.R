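test_that("level discretization is equal-width, monotone and degenerate-safe", {
  expect_equal(discretize_levels(c(0, 1, 2, 3, 4)), c(1L, 2L, 3L, 4L, 5L))
  expect_warning(lev <- discretize_levels(rep(2, 6)), "zero value range")
  expect_equal(lev, rep(1L, 6))
  v <- sort(runif(30))
  expect_true(all(diff(discretize_levels(v)) >= 0))
  # shared range shifts levels coherently
  lv <- discretize_levels(c(0, 0.5, 1), value_range = c(0, 2))
  expect_equal(lv, c(1L, 2L, 3L))
})

test_that("radar tables stack leveled curves with consistent binning", {
  models <- default_response_models()
  curves <- lapply(models, analytic_curve)
  tab <- build_radar_table(curves, cell_type = "demo")
  expect_equal(dim(tab), c(5L, 8L))
  expect_true(all(tab >= 1 & tab <= 5))
  tab1 <- build_radar_table(curves[1], cell_type = "one")
  expect_equal(nrow(tab1), 1L)
  # flat-response type scores all level 1
  flat <- lapply(default_response_models(amplitude_scale = 0), analytic_curve)
  tabf <- suppressWarnings(build_radar_table(flat, cell_type = "flat"))
  expect_true(all(tabf == 1L))
  # mismatched bins error
  c_bad <- analytic_curve(models[[1]], size_range = c(0.2, 20))
  expect_error(build_radar_table(list(a = curves[[1]], b = c_bad)),
               "mismatched")
})

test_that("optimal feature size finds engineered peaks and obeys the tie rule", {
  # alignment engineered at 200 nm, recovered from a generator round-trip
  topo <- exponential_profile()
  cal <- fit_size_calibration(topo)
  m <- response_model("axonal_alignment", 0.2, noise_sd = 0.1)
  sc <- make_scene(topo, m, density_per_cm2 = 5000, void_fraction = 0.2,
                   seed = 31, height_um = 10000)
  obs <- scene_observations(sc)
  surf <- fit_surface(obs, list(length_scales = c(800, 3000), signal_var = 0.3,
                                noise_var = 0.01, kernel = "se"),
                      max_train = 400)
  g <- predict_grid(surf, total_points = 10000)
  cv <- marginalize_to_size_curve(g, cal, 8, size_range = c(0.1, 20))
  opt <- optimal_feature_size(cv)
  expect_true(cv$size_lo_um[opt$bin] <= 0.2 && 0.2 <= cv$size_hi_um[opt$bin])
  # monotone increasing curve: largest bin
  inc <- analytic_curve(response_model("adhesion", 1e6, log_width = 5))
  expect_equal(optimal_feature_size(inc)$bin, 8L)
  # constant curve: smallest bin by the tie rule
  cst <- analytic_curve(response_model("adhesion", 1, amplitude = 0))
  expect_equal(optimal_feature_size(cst)$bin, 1L)
  # invariance under a strictly monotone transform
  tr <- cst; tr$mean <- exp(tr$mean)
  expect_equal(optimal_feature_size(tr)$bin, 1L)
  pk <- analytic_curve(response_model("axonal_growth", 5))
  pk2 <- pk; pk2$mean <- 3 * pk$mean + 7
  expect_equal(optimal_feature_size(pk2)$bin, optimal_feature_size(pk)$bin)
})

test_that("sensitivity index measures level range and respects amplitude", {
  m <- matrix(3L, 5, 8)
  rownames(m) <- letters[1:5]
  tab <- structure(m, class = c("radar_table", class(m)),
                   bin_edges = exp(seq(log(0.1), log(20), length.out = 9)),
                   n_levels = 5L)
  s <- sensitivity_index(tab)
  expect_true(all(s$per_behavior == 0))
  expect_equal(s$overall, 0)
  m2 <- m; m2[1, ] <- c(1L, 2L, 3L, 4L, 5L, 4L, 3L, 2L)
  tab2 <- structure(m2, class = c("radar_table", class(m2)),
                    bin_edges = attr(tab, "bin_edges"), n_levels = 5L)
  expect_equal(sensitivity_index(tab2)$per_behavior[["a"]], 4)
  # location invariance: adding a constant with a matching shared range
  models <- default_response_models()
  curves <- lapply(models, analytic_curve)
  shifted <- lapply(curves, function(c) { c$mean <- c$mean + 10; c })
  r1 <- lapply(curves, function(c) range(c$mean))
  r2 <- lapply(shifted, function(c) range(c$mean))
  t1 <- build_radar_table(curves, value_ranges = r1)
  t2 <- build_radar_table(shifted, value_ranges = r2)
  expect_equal(sensitivity_index(t1), sensitivity_index(t2))
  # non-decreasing in amplitude under shared standards
  hi <- lapply(default_response_models(1), analytic_curve)
  lo <- lapply(default_response_models(0.5), analytic_curve)
  rng <- shared_value_ranges(list(hi = hi, lo = lo))
  th <- build_radar_table(hi, value_ranges = rng)
  tl <- build_radar_table(lo, value_ranges = rng)
  expect_gte(sensitivity_index(th)$overall, sensitivity_index(tl)$overall)
})

test_that("cell-type comparison recovers engineered differences", {
  mk <- function(peaks, amp = 1) {
    ms <- default_response_models(amplitude_scale = amp)
    for (b in names(peaks)) ms[[b]]$peak_size_um <- peaks[[b]]
    lapply(ms, analytic_curve)
  }
  types <- list(
    typeA = mk(list(axonal_growth = 5)),
    typeB = mk(list(axonal_growth = 0.5)),
    typeC = mk(list(axonal_growth = 15)))
  rng <- shared_value_ranges(types)
  tabs <- lapply(names(types), function(t)
    build_radar_table(types[[t]], cell_type = t, value_ranges = rng))
  names(tabs) <- names(types)
  cmp <- compare_cell_types(tabs)
  opt <- cmp$optimal
  ga <- opt[opt$behavior == "axonal_growth", ]
  peak_bin <- function(p) findInterval(p, attr(tabs[[1]], "bin_edges"),
                                       rightmost.closed = TRUE)
  expect_equal(ga$best_bin[ga$cell_type == "typeA"], peak_bin(5))
  expect_equal(ga$best_bin[ga$cell_type == "typeB"], peak_bin(0.5))
  expect_equal(ga$best_bin[ga$cell_type == "typeC"], peak_bin(15))
  # identical tables: all pairwise differences zero
  cmp2 <- compare_cell_types(list(a = tabs[[1]], b = tabs[[1]]))
  expect_true(all(cmp2$pairwise[[1]] == 0))
  expect_error(compare_cell_types(tabs[1]), "at least 2")
  # mismatched binning errors
  other <- build_radar_table(mk(list())["adhesion"], cell_type = "x")
  expect_error(compare_cell_types(list(a = tabs[[1]], b = other)),
               "mismatched")
})
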