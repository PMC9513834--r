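#' Interferometer geometry for gradient interference lithography
#'
#' Describes the two-beam exposure: a collimated UV beam that reaches the
#' photoresist directly at grazing angle `beam_angle_deg` from the substrate
#' plane, and the same beam folded onto the substrate by a curved
#' (cylindrical, circular-arc cross-section) mirror of focal length
#' `focal_length_mm`. The arc radius is `2 * focal_length_mm`. A flat mirror
#' (classical Lloyd configuration, single uniform period) is selected by
#' `focal_length_mm = Inf`.
#'
#' Substrate positions handed to [trace_reflected_angle()], [local_period()]
#' and [build_topography_profile()] are exposure coordinates in micrometres:
#' the origin sits at the initial point of exposure, i.e. the edge of the
#' illuminated gradient region (plus a small edge inset, see
#' [build_topography_profile()]). `mirror_offset_mm` overrides this
#' self-alignment with an explicit placement of the substrate origin
#' relative to the mirror foot.
#'
#' @param wavelength_nm laser wavelength in nanometres (default 325, He-Cd).
#' @param beam_angle_deg angle beta between the static beam and the substrate
#'   plane, in degrees, strictly inside (0, 90).
#' @param focal_length_mm focal length f of the curved mirror in millimetres;
#'   the mirror is a circular arc of radius `2 * f`. `Inf` selects the flat
#'   Lloyd's mirror.
#' @param mirror_curvature_sign `"concave"` (default) or `"convex"`.
#' @param substrate_length_mm usable substrate length in millimetres.
#' @param mirror_offset_mm optional signed placement (mm) of the substrate
#'   origin relative to the mirror foot; `NA` (default) self-aligns the
#'   origin to the illuminated gradient edge.
#' @return an object of class `"interferometer_geometry"`.
#' @export
interferometer_geometry <- function(wavelength_nm = 325,
                                    beam_angle_deg = 67,
                                    focal_length_mm = 10,
                                    mirror_curvature_sign = c("concave", "convex"),
                                    substrate_length_mm = 10,
                                    mirror_offset_mm = NA_real_) {
  mirror_curvature_sign <- match.arg(mirror_curvature_sign)
  stopifnot(
    is.numeric(wavelength_nm), length(wavelength_nm) == 1L, wavelength_nm > 0,
    is.numeric(beam_angle_deg), length(beam_angle_deg) == 1L,
    beam_angle_deg > 0, beam_angle_deg < 90,
    is.numeric(focal_length_mm), length(focal_length_mm) == 1L, focal_length_mm > 0,
    is.numeric(substrate_length_mm), substrate_length_mm > 0
  )
  structure(list(
    wavelength_nm = wavelength_nm,
    beam_angle_deg = beam_angle_deg,
    focal_length_mm = focal_length_mm,
    mirror_curvature_sign = mirror_curvature_sign,
    substrate_length_mm = substrate_length_mm,
    mirror_offset_mm = mirror_offset_mm
  ), class = "interferometer_geometry")
}

#' @export
print.interferometer_geometry <- function(x, ...) {
  cat(sprintf(
    "Interferometer geometry: lambda = %g nm, beta = %g deg, f = %s mm (%s)\n",
    x$wavelength_nm, x$beam_angle_deg,
    if (is.infinite(x$focal_length_mm)) "Inf (flat Lloyd mirror)" else
      format(x$focal_length_mm),
    x$mirror_curvature_sign))
  cat(sprintf("  substrate %g mm, mirror offset %s mm\n",
              x$substrate_length_mm,
              if (is.na(x$mirror_offset_mm)) "auto (exposure-aligned)" else
                format(x$mirror_offset_mm)))
  invisible(x)
}

# Mounting convention: the arc centre sits at elevation MIRROR_ELEVATION_DEG
# above the substrate plane, at distance R = 2f from the mirror foot (the
# point where the arc meets the plane). The incoming beam travels towards
# -x at `beta` below horizontal. Fixed once for the package; see the methods
# vignette for how this constant was chosen.
MIRROR_ELEVATION_DEG <- 30

# Exposure edge margin (mm): profiles start this far inside the illuminated
# branch so the co-propagation divergence at the branch edge is excluded.
EDGE_INSET_MM <- 0.1

#' Ray-trace the mirror fan of a curved-mirror geometry
#'
#' Dense sweep over the arc; returns one row per arc sample that is front-lit
#' and reflects downward onto the substrate plane.
#'
#' @return data.frame with arc parameter `phi`, landing abscissa `x_mm`
#'   (mirror frame: mirror foot at 0), reflected unit-direction components
#'   `vx`, `vy`, mirror-point height `py_mm`, and the interference angle sum
#'   `ssum = cos(beta) + vx` (signed; 0 means co-propagation with the direct
#'   beam, 2 cos(beta) the flat-Lloyd value).
#' @noRd
.mirror_fan <- function(geometry, n = 20000L) {
  beta <- geometry$beam_angle_deg * pi / 180
  R <- 2 * geometry$focal_length_mm
  gam <- MIRROR_ELEVATION_DEG * pi / 180
  u <- c(-cos(beta), -sin(beta))
  concave <- geometry$mirror_curvature_sign == "concave"
  C <- if (concave) R * c(cos(gam), sin(gam)) else R * c(cos(gam), -sin(gam))
  phi <- seq(-pi, pi, length.out = n)
  px <- C[1] + R * cos(phi)
  py <- C[2] + R * sin(phi)
  if (concave) {
    nx <- (C[1] - px) / R; ny <- (C[2] - py) / R
  } else {
    nx <- (px - C[1]) / R; ny <- (py - C[2]) / R
  }
  udn <- u[1] * nx + u[2] * ny
  vx <- u[1] - 2 * udn * nx
  vy <- u[2] - 2 * udn * ny
  ok <- udn < 0 & vy < 0 & py > 0
  x_mm <- px + py * (vx / (-vy))
  d <- data.frame(phi = phi, x_mm = x_mm, vx = vx, vy = vy, py_mm = py)[ok, ]
  d <- d[is.finite(d$x_mm), ]
  d$ssum <- cos(beta) + d$vx
  d
}

# Split the fan into branches monotone in landing position and return the
# gradient branch: the one sweeping the widest range of the interference
# angle sum (from co-propagation, ssum ~ 0, towards the specular Lloyd value).
.gradient_branch <- function(geometry) {
  d <- .mirror_fan(geometry)
  if (nrow(d) < 10L)
    stop("geometry produces no illuminated substrate region")
  d <- d[order(d$phi), ]
  br <- cumsum(c(1, 1, abs(diff(sign(diff(d$x_mm)))) > 0))[seq_len(nrow(d))]
  rng <- tapply(d$ssum, br, function(s) diff(range(s)))
  pick <- as.integer(names(rng)[which.max(rng)])
  dd <- d[br == pick, ]
  dd[order(dd$x_mm), ]
}

# Mirror-frame abscissa (mm) of the substrate origin for a geometry:
# user-specified mirror_offset_mm, or the illuminated gradient edge plus the
# exposure inset. Orientation: exposure x grows in the direction of
# increasing |ssum| (decreasing period); `dir` is +1/-1 in the mirror frame.
.exposure_frame <- function(geometry, branch = .gradient_branch(geometry)) {
  i_min <- which.min(abs(branch$ssum))
  dir <- if (i_min <= nrow(branch) / 2) 1 else -1
  edge <- if (dir > 0) min(branch$x_mm) else max(branch$x_mm)
  x0 <- if (is.na(geometry$mirror_offset_mm)) edge + dir * EDGE_INSET_MM
        else geometry$mirror_offset_mm
  illum_len <- diff(range(branch$x_mm)) -
    (if (is.na(geometry$mirror_offset_mm)) 2 * EDGE_INSET_MM else 0)
  list(x0_mm = x0, dir = dir, illum_len_mm = max(illum_len, 0), branch = branch)
}

#' Reflected-beam angle at a substrate position
#'
#' Traces which arc point sends a mirror-reflected ray to the substrate
#' position `x_um` (exposure coordinates) and returns the elevation angle of
#' that ray's direction of travel, measured from the substrate plane in
#' degrees on (0, 180): values below 90 propagate towards +x, values above 90
#' towards -x like the direct beam (which travels at `180 - beta`). For a
#' flat mirror (`focal_length_mm = Inf`) the specular Lloyd value `beta` is
#' returned for every position.
#'
#' @param geometry an [interferometer_geometry()].
#' @param x_um numeric vector of substrate positions, micrometres.
#' @return numeric vector of angles in degrees.
#' @export
trace_reflected_angle <- function(geometry, x_um) {
  stopifnot(inherits(geometry, "interferometer_geometry"), is.numeric(x_um))
  if (is.infinite(geometry$focal_length_mm)) {
    bad <- x_um < 0 | x_um > geometry$substrate_length_mm * 1000
    if (any(bad))
      stop(sprintf("position not illuminated: x = %g um outside the substrate",
                   x_um[which(bad)[1L]]))
    return(rep(geometry$beam_angle_deg, length(x_um)))
  }
  fr <- .exposure_frame(geometry)
  b <- fr$branch
  x_mm <- fr$x0_mm + fr$dir * x_um / 1000
  lo <- min(b$x_mm); hi <- max(b$x_mm)
  out <- numeric(length(x_um))
  beta <- geometry$beam_angle_deg * pi / 180
  R <- 2 * geometry$focal_length_mm
  gam <- MIRROR_ELEVATION_DEG * pi / 180
  concave <- geometry$mirror_curvature_sign == "concave"
  C <- if (concave) R * c(cos(gam), sin(gam)) else R * c(cos(gam), -sin(gam))
  u <- c(-cos(beta), -sin(beta))
  land <- function(phi) {
    px <- C[1] + R * cos(phi); py <- C[2] + R * sin(phi)
    s <- if (concave) 1 else -1
    nx <- s * (C[1] - px) / R; ny <- s * (C[2] - py) / R
    udn <- u[1] * nx + u[2] * ny
    vx <- u[1] - 2 * udn * nx; vy <- u[2] - 2 * udn * ny
    list(x = px + py * (vx / (-vy)), vx = vx, vy = vy)
  }
  for (i in seq_along(x_um)) {
    xi <- x_mm[i]
    if (!is.finite(xi) || xi < lo - 1e-9 || xi > hi + 1e-9)
      stop(sprintf("position not illuminated: x = %g um", x_um[i]))
    j <- findInterval(xi, b$x_mm, all.inside = TRUE)
    phi <- tryCatch(
      stats::uniroot(function(p) land(p)$x - xi,
                     lower = min(b$phi[j], b$phi[j + 1L]),
                     upper = max(b$phi[j], b$phi[j + 1L]),
                     extendInt = "yes", tol = 1e-12)$root,
      error = function(e) NA_real_)
    if (is.na(phi)) {  # fall back to the sweep sample nearest the position
      phi <- b$phi[which.min(abs(b$x_mm - xi))]
    }
    v <- land(phi)
    out[i] <- atan2(-v$vy, v$vx) * 180 / pi
  }
  out
}

#' Two-beam grating period
#'
#' The interference fringe period `lambda / (sin(theta1) + sin(theta2))` for
#' beam angles measured from the substrate normal. Angles are signed: equal
#' signs mean the two beams arrive from opposite sides (counter-propagating
#' transverse components, the classical Lloyd case); opposite signs mean
#' same-side, nearly co-propagating beams whose fringe period diverges as
#' the sum approaches zero.
#'
#' @param wavelength_nm wavelength in nanometres.
#' @param theta1_deg,theta2_deg beam angles from the substrate normal,
#'   degrees, signed.
#' @return period in micrometres.
#' @export
grating_period <- function(wavelength_nm, theta1_deg, theta2_deg) {
  s <- sin(theta1_deg * pi / 180) + sin(theta2_deg * pi / 180)
  degen <- abs(s) < 1e-9
  if (any(degen)) {
    warning("degenerate co-propagating interference: period clamped")
    s[degen] <- 1e-9
  }
  (wavelength_nm * 1e-3) / abs(s)
}

#' Local fringe period along the gradient array
#'
#' Combines the direct beam (angle `90 - beta` from the substrate normal)
#' with the traced mirror beam through the grating equation. Periods can
#' never fall below `lambda / 2` (two-beam diffraction limit) and diverge
#' where the mirror beam co-propagates with the direct beam.
#'
#' @inheritParams trace_reflected_angle
#' @return local period in micrometres, one value per position.
#' @export
local_period <- function(geometry, x_um) {
  alpha2 <- trace_reflected_angle(geometry, x_um)
  theta1 <- 90 - geometry$beam_angle_deg          # direct beam, from normal
  theta2 <- 90 - alpha2                           # signed: <0 when same-side
  grating_period(geometry$wavelength_nm, theta1, theta2)
}

#' Duty cycle of a thresholded sinusoidal exposure dose
#'
#' For dose `D(u) = mean_dose + visibility * cos(2 pi u)` over one fringe
#' period, returns the developed line fraction: the fraction of the period
#' where the dose exceeds (negative tone) or falls below (positive tone) the
#' development threshold. Closed form
#' `acos((threshold - mean_dose) / visibility) / pi`, clipped to \[0, 1\].
#'
#' @param mean_dose,visibility,threshold dose parameters (same arbitrary
#'   units); `visibility >= 0`.
#' @param resist_tone `"negative"` (exposed resist stays) or `"positive"`.
#' @return duty cycle in \[0, 1\].
#' @export
fringe_duty_cycle <- function(mean_dose, visibility, threshold,
                              resist_tone = c("negative", "positive")) {
  resist_tone <- match.arg(resist_tone)
  stopifnot(all(visibility >= 0))
  n <- max(length(mean_dose), length(visibility), length(threshold))
  mean_dose <- rep_len(mean_dose, n); visibility <- rep_len(visibility, n)
  threshold <- rep_len(threshold, n)
  d <- numeric(n)
  zero <- visibility == 0
  if (any(zero)) {
    warning("zero fringe visibility: duty cycle is all-or-nothing")
    d[zero] <- as.numeric(mean_dose[zero] > threshold[zero])
  }
  r <- pmin(1, pmax(-1, (threshold[!zero] - mean_dose[!zero]) / visibility[!zero]))
  d[!zero] <- acos(r) / pi
  if (resist_tone == "positive") d <- 1 - d
  d
}

#' Simulate the gradient topography profile written by a geometry
#'
#' Samples the illuminated substrate, computes the local fringe period by
#' ray tracing, and models resist development with a thresholded sinusoidal
#' dose whose fringe visibility follows the local mirror-beam amplitude
#' (energy spread of the fan). The development threshold is set so the
#' widest-period position develops at duty cycle 0.5.
#'
#' @param geometry an [interferometer_geometry()].
#' @param n_samples number of positions (>= 2).
#' @param height_um constant pattern height (resist thickness), micrometres.
#' @param resist_tone passed to [fringe_duty_cycle()].
#' @return a `topography_profile`: data.frame with columns `position_um`,
#'   `period_um`, `linewidth_um`, `duty_cycle`, `height_um`.
#' @export
build_topography_profile <- function(geometry, n_samples = 400L,
                                     height_um = 0.3,
                                     resist_tone = "negative") {
  stopifnot(inherits(geometry, "interferometer_geometry"), n_samples >= 2L)
  L_sub <- geometry$substrate_length_mm * 1000
  if (is.infinite(geometry$focal_length_mm)) {
    pos <- seq(0, L_sub, length.out = n_samples)
    per <- local_period(geometry, pos)
    duty <- rep(0.5, n_samples)
  } else {
    fr <- .exposure_frame(geometry)
    if (fr$illum_len_mm <= 0)
      stop("geometry produces no illuminated substrate region")
    L <- min(L_sub, fr$illum_len_mm * 1000)
    pos <- seq(0, L, length.out = n_samples)
    per <- local_period(geometry, pos)
    # fringe visibility from the fan's energy spread: mirror-beam relative
    # amplitude ~ sqrt(arc length per unit landing length)
    b <- fr$branch
    w <- abs(diff(b$phi) / diff(b$x_mm))
    xw <- (b$x_mm[-1] + b$x_mm[-nrow(b)]) / 2
    x_mm <- fr$x0_mm + fr$dir * pos / 1000
    wi <- stats::approx(xw, w, xout = x_mm, rule = 2, ties = mean)$y
    a <- sqrt(wi / max(wi, na.rm = TRUE))
    mean_dose <- 1 + a^2
    vis <- 2 * a
    thr <- mean_dose[which.max(per)]    # duty 0.5 at the widest period
    duty <- fringe_duty_cycle(mean_dose, vis, thr, resist_tone)
  }
  if (any(per < geometry$wavelength_nm * 1e-3 / 2 - 1e-12))
    stop("internal error: period below the two-beam diffraction limit")
  structure(
    data.frame(position_um = pos, period_um = per,
               linewidth_um = duty * per, duty_cycle = duty,
               height_um = height_um),
    class = c("topography_profile", "data.frame"),
    geometry = geometry, synthetic = FALSE)
}

#' Idealized exponential gradient profile
#'
#' A synthetic topography whose period decays exactly exponentially with
#' position, emulating the printed feature-size range of the fabricated
#' gradient array (20 um down to 0.1 um across 1 cm by default). Used as the
#' default substrate of the synthetic-data generator and for exact
#' calibration tests.
#'
#' @param period_start_um,period_end_um periods at the two substrate ends.
#' @param length_um substrate length, micrometres.
#' @param n_samples number of samples.
#' @param duty_cycle constant duty cycle.
#' @param height_um constant pattern height.
#' @return a `topography_profile` (attribute `synthetic = TRUE`).
#' @export
exponential_profile <- function(period_start_um = 20, period_end_um = 0.1,
                                length_um = 10000, n_samples = 400L,
                                duty_cycle = 0.5, height_um = 0.3) {
  stopifnot(period_start_um > 0, period_end_um > 0, length_um > 0,
            n_samples >= 2L, duty_cycle >= 0, duty_cycle <= 1)
  pos <- seq(0, length_um, length.out = n_samples)
  k <- log(period_end_um / period_start_um) / length_um
  per <- period_start_um * exp(k * pos)
  structure(
    data.frame(position_um = pos, period_um = per,
               linewidth_um = duty_cycle * per, duty_cycle = duty_cycle,
               height_um = height_um),
    class = c("topography_profile", "data.frame"),
    geometry = NULL, synthetic = TRUE)
}

#' Write a topography profile to CSV
#' @param profile a `topography_profile`.
#' @param path output file.
#' @export
write_topography_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
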