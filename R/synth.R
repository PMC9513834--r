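#' Seed-scoped random evaluation
#'
#' Runs `expr` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards, so generator calls are reproducible without disturbing
#' the session.
#' @noRd
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Deterministic sub-seed derivation
#'
#' Fans one master seed out into reproducible per-stage seeds via a
#' polynomial string hash, keeping every derived seed a valid 32-bit
#' integer.
#'
#' @param master integer master seed.
#' @param ... stage tags (coerced to character) identifying the consumer.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
sub_seed <- function(master, ...) {
  tags <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- as.numeric(master) %% 2147483647
  for (c in utf8ToInt(tags)) h <- (h * 31 + c) %% 2147483647
  as.integer(max(1, h))
}

#' Peaked feature-size response model for one cell behavior
#'
#' Behavior value as a function of local feature size `s`:
#' `baseline + amplitude * exp(-(log s - log peak_size)^2 / (2 log_width^2))`
#' plus Gaussian measurement noise. The log-Gaussian family captures the
#' unimodal responses seen across behaviors (e.g. axonal growth peaking at
#' 5 um lines); monotone responses such as adhesion favoring the largest
#' lines are modelled by placing the peak at the range edge.
#'
#' @param behavior_name one of `"adhesion"`, `"proliferation"`,
#'   `"differentiation"`, `"axonal_growth"`, `"axonal_alignment"`.
#' @param peak_size_um feature size of maximal response, micrometres.
#' @param log_width response spread in natural-log size units.
#' @param amplitude,baseline response units.
#' @param noise_sd measurement noise standard deviation, response units.
#' @return a `response_model`.
#' @export
response_model <- function(behavior_name, peak_size_um, log_width = 0.6,
                           amplitude = 1, baseline = 0.2, noise_sd = 0.15) {
  behavior_name <- match.arg(behavior_name, c(
    "adhesion", "proliferation", "differentiation",
    "axonal_growth", "axonal_alignment"))
  stopifnot(peak_size_um > 0, log_width > 0, amplitude >= 0, noise_sd >= 0)
  structure(list(behavior_name = behavior_name, peak_size_um = peak_size_um,
                 log_width = log_width, amplitude = amplitude,
                 baseline = baseline, noise_sd = noise_sd),
            class = "response_model")
}

#' Default response models for the five screened behaviors
#'
#' Peak sizes follow the screening read-outs: adhesion favors the largest
#' (20 um) lines, axonal growth peaks at 5 um, axonal alignment favors
#' nanoscale (0.2 um) lines; proliferation and differentiation sit at
#' intermediate scales. `amplitude_scale` rescales every amplitude, which is
#' how an impaired-mechanosensitivity ("patient") cell type is emulated.
#'
#' @param amplitude_scale multiplier on all amplitudes.
#' @param noise_sd measurement noise for all behaviors.
#' @return named list of [response_model()]s.
#' @export
default_response_models <- function(amplitude_scale = 1, noise_sd = 0.15) {
  peaks <- c(adhesion = 20, proliferation = 1, differentiation = 2,
             axonal_growth = 5, axonal_alignment = 0.2)
  out <- lapply(names(peaks), function(b)
    response_model(b, peaks[[b]], amplitude = amplitude_scale,
                   noise_sd = noise_sd))
  names(out) <- names(peaks)
  out
}

#' Noiseless response of a model at given feature sizes
#' @param model a [response_model()].
#' @param size_um feature sizes, micrometres.
#' @return expected behavior values.
#' @export
response_value <- function(model, size_um) {
  stopifnot(inherits(model, "response_model"))
  z <- (log(size_um) - log(model$peak_size_um)) / model$log_width
  model$baseline + model$amplitude * exp(-z^2 / 2)
}

# Sample non-overlapping axis-aligned void rectangles until the requested
# area fraction is reached (cell-free regions: the false-null failure mode).
.sample_voids <- function(width_um, height_um, void_fraction, max_try = 400L) {
  voids <- data.frame(x0 = numeric(), x1 = numeric(),
                      y0 = numeric(), y1 = numeric())
  if (void_fraction <= 0) return(voids)
  target <- void_fraction * width_um * height_um
  acc <- 0
  for (i in seq_len(max_try)) {
    if (acc >= target) break
    w <- stats::runif(1, 0.08, 0.22) * width_um
    h <- stats::runif(1, 0.08, 0.22) * height_um
    x0 <- stats::runif(1, 0, width_um - w)
    y0 <- stats::runif(1, 0, height_um - h)
    overlap <- nrow(voids) > 0 &&
      any(x0 < voids$x1 & x0 + w > voids$x0 &
          y0 < voids$y1 & y0 + h > voids$y0)
    if (overlap) next
    excess <- (acc + w * h) - target
    if (excess > 0 && excess > 0.5 * w * h) next
    voids <- rbind(voids, data.frame(x0 = x0, x1 = x0 + w,
                                     y0 = y0, y1 = y0 + h))
    acc <- acc + w * h
  }
  voids
}

.in_void <- function(x, y, voids) {
  if (nrow(voids) == 0L) return(rep(FALSE, length(x)))
  inside <- rep(FALSE, length(x))
  for (i in seq_len(nrow(voids)))
    inside <- inside | (x >= voids$x0[i] & x <= voids$x1[i] &
                        y >= voids$y0[i] & y <= voids$y1[i])
  inside
}

#' Sample cell positions on the array
#'
#' Homogeneous Poisson point process over the non-void area of the
#' substrate: the expected count is `density_per_cm2` times the non-void
#' area. Void rectangles emulate cell-free regions.
#'
#' @param topography a `topography_profile` defining the x-extent.
#' @param density_per_cm2 seeding density (cells per cm^2); screening used
#'   10,000 (adhesion/growth) or 40,000 (differentiation) cells per cm^2.
#' @param void_fraction fraction of the area covered by cell-free
#'   rectangles, in `[0, 1)`.
#' @param seed integer seed; identical seeds give identical output.
#' @param height_um y-extent of the observed field, micrometres.
#' @return list with `positions` (data.frame `x_um`, `y_um`) and `voids`.
#' @export
sample_cell_positions <- function(topography, density_per_cm2 = 10000,
                                  void_fraction = 0.3, seed = 1L,
                                  height_um = NULL) {
  stopifnot(inherits(topography, "topography_profile"),
            density_per_cm2 >= 0)
  if (void_fraction < 0 || void_fraction >= 1)
    stop("void_fraction must be in [0, 1)")
  width_um <- diff(range(topography$position_um))
  if (is.null(height_um)) height_um <- width_um
  with_seed(seed, {
    voids <- .sample_voids(width_um, height_um, void_fraction)
    void_area <- if (nrow(voids)) sum((voids$x1 - voids$x0) *
                                      (voids$y1 - voids$y0)) else 0
    lam <- density_per_cm2 * (width_um * height_um - void_area) / 1e8
    n <- stats::rpois(1, lam)
    xs <- numeric(0); ys <- numeric(0)
    while (length(xs) < n) {
      m <- max(16L, 2L * (n - length(xs)))
      x <- stats::runif(m, 0, width_um) + min(topography$position_um)
      y <- stats::runif(m, 0, height_um)
      keep <- !.in_void(x - min(topography$position_um), y, voids)
      xs <- c(xs, x[keep]); ys <- c(ys, y[keep])
    }
    list(positions = data.frame(x_um = xs[seq_len(n)], y_um = ys[seq_len(n)]),
         voids = voids, height_um = height_um)
  })
}

#' Attach behavior values to sampled positions
#'
#' Evaluates the response model at each cell's local feature size (from the
#' topography) and adds Gaussian measurement noise. True noiseless values
#' are kept for recovery tests.
#'
#' @param positions data.frame with `x_um`, `y_um` (from
#'   [sample_cell_positions()]).
#' @param topography the `topography_profile` the positions live on.
#' @param model a [response_model()].
#' @param seed integer seed for the noise draw.
#' @return an `observation_set`: data.frame `x_um`, `y_um`, `z`, `z_true`,
#'   `size_um` with attributes `behavior_name`, `model`, `provenance`.
#' @export
sample_behavior_values <- function(positions, topography, model, seed = 1L) {
  stopifnot(inherits(model, "response_model"))
  size <- stats::approx(topography$position_um, topography$period_um,
                        xout = positions$x_um, rule = 2, ties = mean)$y
  z_true <- response_value(model, size)
  z <- with_seed(seed, z_true + stats::rnorm(length(z_true), 0, model$noise_sd))
  structure(
    data.frame(x_um = positions$x_um, y_um = positions$y_um,
               z = z, z_true = z_true, size_um = size),
    class = c("observation_set", "data.frame"),
    behavior_name = model$behavior_name, model = model,
    provenance = "per_cell", cell_type = NA_character_)
}

#' Generate a full synthetic scene for one behavior
#'
#' Convenience wrapper: positions, voids, behavior values and per-cell
#' rendering parameters (area, eccentricity, orientation) in one object.
#' For the `axonal_alignment` behavior, cell orientation concentrates
#' around the line direction (0 degrees) with spread shrinking as the local
#' response grows, so orientation analysis sees a real alignment signal.
#'
#' @inheritParams sample_cell_positions
#' @param model a [response_model()].
#' @param seed master seed for the scene (positions, noise, shapes).
#' @return a `synthetic_scene` list.
#' @export
make_scene <- function(topography, model, density_per_cm2 = 10000,
                       void_fraction = 0.3, seed = 1L, height_um = NULL) {
  pos <- sample_cell_positions(topography, density_per_cm2, void_fraction,
                               seed = sub_seed(seed, "positions"),
                               height_um = height_um)
  obs <- sample_behavior_values(pos$positions, topography, model,
                                seed = sub_seed(seed, "noise"))
  n <- nrow(obs)
  shp <- with_seed(sub_seed(seed, "shapes"), {
    area <- stats::rlnorm(n, meanlog = log(15), sdlog = 0.25)   # um^2
    ecc <- stats::rbeta(n, 2, 2)
    if (model$behavior_name == "axonal_alignment") {
      resp <- pmin(1, pmax(0, (obs$z_true - model$baseline) /
                                max(model$amplitude, 1e-9)))
      sdo <- 40 * (1 - 0.9 * resp)
      ori <- stats::rnorm(n, 0, sdo)
      ori <- ((ori + 90) %% 180) - 90
    } else {
      ori <- stats::runif(n, -90, 90)
    }
    data.frame(area_um2 = area, eccentricity = ecc, orientation_deg = ori)
  })
  cells <- cbind(id = seq_len(n), obs, shp)
  structure(list(topography = topography, cells = cells,
                 void_regions = pos$voids, seed = seed,
                 density_per_cm2 = density_per_cm2,
                 height_um = pos$height_um, model = model),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene: %d cells, %d void regions, behavior '%s'\n",
              nrow(x$cells), nrow(x$void_regions), x$model$behavior_name))
  invisible(x)
}

#' Write a scene's cell table to CSV
#' @param scene a `synthetic_scene`.
#' @param path output file.
#' @export
write_scene_csv <- function(scene, path) {
  utils::write.csv(scene$cells, path, row.names = FALSE)
  invisible(path)
}
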