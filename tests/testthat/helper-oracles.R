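# Independent oracles and fixture builders used across the suite.

# Brute-force ray/arc sweep oracle for the reflected angle: finely sample the
# full mirror circle, reflect the incoming plane wave at each front-lit
# sample, and return the elevation angle of the ray landing nearest the
# requested mirror-frame abscissa. Independent of the package's root-solving
# tracer.
oracle_reflected_angle <- function(beta_deg, f_mm, x_mm, n = 2e5) {
  beta <- beta_deg * pi / 180
  R <- 2 * f_mm
  gam <- 30 * pi / 180            # package mounting convention
  u <- c(-cos(beta), -sin(beta))
  C <- R * c(cos(gam), sin(gam))
  phi <- seq(-pi, pi, length.out = n)
  px <- C[1] + R * cos(phi); py <- C[2] + R * sin(phi)
  nx <- (C[1] - px) / R; ny <- (C[2] - py) / R
  udn <- u[1] * nx + u[2] * ny
  vx <- u[1] - 2 * udn * nx; vy <- u[2] - 2 * udn * ny
  ok <- udn < 0 & vy < 0 & py > 0
  xl <- (px + py * (vx / (-vy)))[ok]
  ang <- atan2(-vy, vx)[ok] * 180 / pi
  ang[which.min(abs(xl - x_mm))]
}

# Duty-cycle "quadrature" oracle: locate the threshold crossings of the
# sinusoidal dose numerically (uniroot to 1e-12) and measure the
# above-threshold fraction of one period.
oracle_duty_cycle <- function(mean_dose, visibility, threshold) {
  f <- function(u) mean_dose + visibility * cos(2 * pi * u) - threshold
  if (f(0) <= 0) return(0)
  if (f(0.5) >= 0) return(1)
  r <- uniroot(f, c(0, 0.5), tol = 1e-14)$root
  2 * r
}

# Digital blob stamp: one hard ellipse of given pixel area at (cx, cy).
stamp_disk <- function(img, cx, cy, area_px, value = 1) {
  r <- sqrt(area_px / pi)
  nx <- nrow(img); ny <- ncol(img)
  ix <- max(1, floor(cx - r - 2)):min(nx, ceiling(cx + r + 2))
  iy <- max(1, floor(cy - r - 2)):min(ny, ceiling(cy + r + 2))
  d2 <- outer((ix - cx)^2, rep(1, length(iy))) +
        outer(rep(1, length(ix)), (iy - cy)^2)
  img[ix, iy][d2 <= r^2] <- value
  img
}

# Small scene fixture on a short idealized gradient.
fixture_scene <- function(behavior = "axonal_growth", peak = 5,
                          density = 10000, voids = 0.3, seed = 1,
                          length_um = 10000, height_um = 10000,
                          noise_sd = 0.15) {
  topo <- exponential_profile(length_um = length_um, n_samples = 200)
  m <- response_model(behavior, peak, noise_sd = noise_sd)
  make_scene(topo, m, density_per_cm2 = density, void_fraction = voids,
             seed = seed, height_um = height_um)
}

scene_observations <- function(scene) {
  structure(scene$cells[, c("x_um", "y_um", "z")],
            class = c("observation_set", "data.frame"),
            behavior_name = scene$model$behavior_name,
            provenance = "per_cell", cell_type = NA_character_)
}

# Axial angular difference in degrees (orientation data on [-90, 90)).
axial_diff <- function(a, b) abs(((a - b + 90) %% 180) - 90)

# Noise-free size-response curve evaluated straight from a response model,
# shaped like marginalize_to_size_curve() output.
analytic_curve <- function(model, n_bins = 8, size_range = c(0.1, 20)) {
  edges <- exp(seq(log(size_range[1]), log(size_range[2]),
                   length.out = n_bins + 1))
  mid <- sqrt(edges[-1] * edges[-length(edges)])
  structure(
    data.frame(bin = seq_len(n_bins), size_lo_um = edges[-length(edges)],
               size_hi_um = edges[-1], size_mid_um = mid,
               mean = response_value(model, mid), sd = 0, n = 1L),
    class = c("size_response_curve", "data.frame"),
    behavior_name = model$behavior_name, cell_type = NA_character_,
    bin_edges = edges)
}
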