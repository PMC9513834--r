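#' Default end-to-end screening configuration
#'
#' Three synthetic cell types (two healthy, one with halved response
#' amplitudes emulating impaired mechanosensitivity) times five behaviors
#' on the idealized 20 um - 0.1 um gradient array. Scale parameters
#' (`grid_points`, `n_iterations`, densities) are modest so a demo run
#' finishes in seconds; raise them for production maps.
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @return a config list consumable by [run_screen()].
#' @export
default_config <- function(seed = 7L, out_dir = tempfile("nanomap_run_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    topography = list(type = "exponential", period_start_um = 20,
                      period_end_um = 0.1, length_um = 10000,
                      n_samples = 400L),
    scene = list(density_per_cm2 = 4000, void_fraction = 0.3,
                 height_um = 2000),
    mapping = list(test_fraction = 0.1, n_iterations = 10L,
                   grid_points = 10000L, max_train = 300L),
    scoring = list(n_levels = 5L, n_size_bins = 8L),
    cell_types = list(
      adult_nsc = list(amplitude_scale = 1, noise_sd = 0.15),
      hipsc_nsc = list(amplitude_scale = 1, noise_sd = 0.15),
      patient_hipsc_nsc = list(amplitude_scale = 0.5, noise_sd = 0.15)),
    behaviors = c("adhesion", "proliferation", "differentiation",
                  "axonal_growth", "axonal_alignment"))
}

#' Validate a screening configuration
#'
#' Applies every range check the pipeline stages rely on before anything
#' runs. Accepts a config list or a YAML file path.
#'
#' @param config list or path to a YAML file.
#' @return a `config_validation`: list with `ok` and `messages`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- tryCatch(yaml::read_yaml(config), error = function(e)
      stop("cannot parse config file: ", conditionMessage(e)))
  }
  msgs <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) msgs <<- c(msgs, msg)
  need(is.numeric(config$seed) && length(config$seed) == 1L,
       "seed: missing or not a single number")
  need(is.character(config$out_dir %||% ""), "out_dir: must be a path")
  tp <- config$topography
  if (identical(tp$type, "exponential")) {
    need(isTRUE(tp$period_start_um > 0) && isTRUE(tp$period_end_um > 0),
         "topography: periods must be positive")
    need(isTRUE(tp$length_um > 0), "topography: length_um must be positive")
  } else if (identical(tp$type, "dlil")) {
    need(isTRUE(tp$beam_angle_deg > 0 && tp$beam_angle_deg < 90),
         "topography: beam_angle_deg must be in (0, 90)")
    need(isTRUE(tp$focal_length_mm > 0),
         "topography: focal_length_mm must be positive")
  } else need(FALSE, "topography: type must be 'exponential' or 'dlil'")
  sc <- config$scene
  need(isTRUE(sc$density_per_cm2 >= 0), "scene: density_per_cm2 must be >= 0")
  need(isTRUE(sc$void_fraction >= 0 && sc$void_fraction < 1),
       "scene: void_fraction must be in [0, 1)")
  mp <- config$mapping
  need(isTRUE(mp$test_fraction > 0 && mp$test_fraction < 1),
       "mapping: test_fraction must be in (0, 1)")
  need(isTRUE(mp$n_iterations >= 0), "mapping: n_iterations must be >= 0")
  need(isTRUE(mp$grid_points >= 4), "mapping: grid_points must be >= 4")
  if (!is.null(mp$n_tiles))
    need(isTRUE(mp$n_tiles >= 48 && mp$n_tiles <= 576),
         "mapping: n_tiles must be between 48 and 576")
  so <- config$scoring
  need(isTRUE(so$n_levels >= 2), "scoring: n_levels must be >= 2")
  need(isTRUE(so$n_size_bins >= 2), "scoring: n_size_bins must be >= 2")
  need(length(config$cell_types) >= 1L, "cell_types: need at least one")
  for (ct in names(config$cell_types)) {
    p <- config$cell_types[[ct]]
    need(isTRUE(p$amplitude_scale >= 0),
         sprintf("cell_types/%s: amplitude_scale must be >= 0", ct))
    need(isTRUE(p$noise_sd >= 0),
         sprintf("cell_types/%s: noise_sd must be >= 0", ct))
  }
  need(length(config$behaviors) >= 1L, "behaviors: need at least one")
  structure(list(ok = length(msgs) == 0L, messages = msgs,
                 config = config), class = "config_validation")
}

#' @export
print.config_validation <- function(x, ...) {
  if (x$ok) cat("Configuration: PASS\n")
  else cat("Configuration: FAIL\n ", paste(x$messages, collapse = "\n  "), "\n")
  invisible(x)
}

.config_topography <- function(tp) {
  if (identical(tp$type, "dlil")) {
    g <- interferometer_geometry(
      wavelength_nm = tp$wavelength_nm %||% 325,
      beam_angle_deg = tp$beam_angle_deg %||% 67,
      focal_length_mm = tp$focal_length_mm %||% 10,
      substrate_length_mm = tp$substrate_length_mm %||% 10)
    build_topography_profile(g, n_samples = tp$n_samples %||% 400L)
  } else {
    exponential_profile(period_start_um = tp$period_start_um %||% 20,
                        period_end_um = tp$period_end_um %||% 0.1,
                        length_um = tp$length_um %||% 10000,
                        n_samples = tp$n_samples %||% 400L)
  }
}

#' Run the full screen: topography, scenes, maps, scores
#'
#' Orchestrates every stage for each cell type and behavior: synthetic
#' scene generation, 90/10 hold-out split, EI-optimized GP surface, dense
#' behavior grid, size-response curve; then radar tables under shared
#' per-behavior scoring standards, sensitivity indices and the cross-type
#' comparison. All artifacts are written under `config$out_dir` and listed
#' in a manifest with per-file checksums; identical config and seed give
#' identical checksums.
#'
#' @param config config list or YAML path (see [default_config()]).
#' @return invisibly, a list with the manifest, per-type curves, radar
#'   tables, comparison and hold-out errors.
#' @export
run_screen <- function(config = default_config()) {
  val <- validate_config(config)
  if (!val$ok)
    stop("invalid configuration:\n  ", paste(val$messages, collapse = "\n  "))
  config <- val$config
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(path, stage, seed = NA_integer_) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = basename(path), stage = stage, seed = seed,
      md5 = unname(tools::md5sum(path)))
  }
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  note(file.path(out_dir, "config.yaml"), "config")

  topo <- .config_topography(config$topography)
  write_topography_csv(topo, file.path(out_dir, "topography.csv"))
  note(file.path(out_dir, "topography.csv"), "optics")
  cal <- fit_size_calibration(topo)

  master <- config$seed
  curves_by_type <- list()
  errors <- list()
  for (ct in names(config$cell_types)) {
    pars <- config$cell_types[[ct]]
    models <- default_response_models(amplitude_scale = pars$amplitude_scale,
                                      noise_sd = pars$noise_sd)
    curves <- list()
    for (b in config$behaviors) {
      seed_b <- sub_seed(master, ct, b)
      scene <- make_scene(topo, models[[b]],
                          density_per_cm2 = config$scene$density_per_cm2,
                          void_fraction = config$scene$void_fraction,
                          seed = seed_b,
                          height_um = config$scene$height_um)
      obs <- structure(scene$cells[, c("x_um", "y_um", "z")],
                       class = c("observation_set", "data.frame"),
                       behavior_name = b, provenance = "per_cell",
                       cell_type = ct)
      sp <- split_holdout(obs, config$mapping$test_fraction,
                          seed = sub_seed(seed_b, "split"))
      hyp <- optimize_hyperparameters(
        sp$train, n_iterations = config$mapping$n_iterations,
        seed = sub_seed(seed_b, "hyper"),
        max_train = config$mapping$max_train)
      surf <- fit_surface(sp$train, hyp,
                          max_train = config$mapping$max_train,
                          seed = sub_seed(seed_b, "fit"))
      err <- holdout_error(surf, sp$test)
      grid <- predict_grid(surf, total_points = config$mapping$grid_points)
      curve <- marginalize_to_size_curve(grid, cal,
                                         config$scoring$n_size_bins,
                                         size_range = range(topo$period_um))
      curves[[b]] <- curve
      errors[[paste(ct, b, sep = "/")]] <- err

      obs_path <- file.path(out_dir, sprintf("obs_%s_%s.csv", ct, b))
      utils::write.csv(scene$cells, obs_path, row.names = FALSE)
      note(obs_path, "synth", seed_b)
      map_path <- file.path(out_dir, sprintf("map_%s_%s.csv", ct, b))
      utils::write.csv(
        data.frame(x_um = rep(grid$x_um, times = length(grid$y_um)),
                   y_um = rep(grid$y_um, each = length(grid$x_um)),
                   z_mean = as.vector(grid$z_mean),
                   z_sd = as.vector(grid$z_sd)),
        map_path, row.names = FALSE)
      note(map_path, "map", seed_b)
    }
    curves_by_type[[ct]] <- curves
  }

  ranges <- shared_value_ranges(curves_by_type)
  tables <- lapply(names(curves_by_type), function(ct)
    build_radar_table(curves_by_type[[ct]], cell_type = ct,
                      n_levels = config$scoring$n_levels,
                      value_ranges = ranges))
  names(tables) <- names(curves_by_type)
  for (ct in names(tables)) {
    p <- file.path(out_dir, sprintf("radar_%s.csv", ct))
    utils::write.csv(as.data.frame(unclass(tables[[ct]])), p)
    note(p, "score")
  }
  comparison <- if (length(tables) >= 2L) compare_cell_types(tables) else NULL
  if (!is.null(comparison)) {
    p <- file.path(out_dir, "comparison_sensitivity.csv")
    utils::write.csv(comparison$sensitivity, p, row.names = FALSE)
    note(p, "score")
    p2 <- file.path(out_dir, "comparison_optimal_sizes.csv")
    utils::write.csv(comparison$optimal, p2, row.names = FALSE)
    note(p2, "score")
  }
  err_df <- data.frame(map = names(errors),
                       rmse = vapply(errors, `[[`, 0, "rmse"),
                       r2 = vapply(errors, `[[`, 0, "r2"),
                       row.names = NULL)
  p <- file.path(out_dir, "holdout_errors.csv")
  utils::write.csv(err_df, p, row.names = FALSE)
  note(p, "map")

  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(list(manifest = manifest, curves = curves_by_type,
                 tables = tables, comparison = comparison,
                 holdout = err_df, out_dir = out_dir))
}
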