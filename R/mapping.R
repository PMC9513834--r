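#' Assemble scattered observations from quantified records
#'
#' Builds the (x, y, z) observation set that the behavior-map regression
#' consumes, from per-cell object tables ([detect_objects()] output) or
#' per-tile intensity tables ([pixelize_intensity()] output). Records with
#' a missing metric are dropped with a message; mixing per-cell and
#' per-tile records is a provenance conflict and errors.
#'
#' @param records a data.frame, or list of data.frames, each with `x_um`,
#'   `y_um` and the metric column.
#' @param metric name of the metric column to use as z.
#' @param behavior_name,cell_type labels carried on the result.
#' @return an `observation_set` data.frame (`x_um`, `y_um`, `z`).
#' @export
assemble_observations <- function(records, metric,
                                  behavior_name = metric,
                                  cell_type = NA_character_) {
  if (is.data.frame(records)) records <- list(records)
  prov <- vapply(records, function(r)
    if ("tile" %in% names(r)) "per_tile" else "per_cell", "")
  if (length(unique(prov)) > 1L)
    stop("provenance conflict: cannot mix per-cell and per-tile records")
  rows <- lapply(records, function(r) {
    if (!metric %in% names(r))
      stop(sprintf("metric '%s' missing from records", metric))
    data.frame(x_um = r$x_um, y_um = r$y_um, z = r[[metric]])
  })
  out <- do.call(rbind, rows)
  bad <- !is.finite(out$z) | !is.finite(out$x_um) | !is.finite(out$y_um)
  if (any(bad)) {
    message(sprintf("assemble_observations: dropped %d record(s) with missing values",
                    sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) < 10L)
    stop(sprintf("need at least 10 usable observations, got %d", nrow(out)))
  rownames(out) <- NULL
  structure(out, class = c("observation_set", "data.frame"),
            behavior_name = behavior_name, provenance = prov[1L],
            cell_type = cell_type)
}

#' Hold-out split of an observation set
#'
#' Uniform random split without replacement into training and testing
#' subsets (default 90% / 10% hold-out cross-validation). The test count is
#' `round(n * test_fraction)`, at least 1; the split is exhaustive and
#' disjoint and reproducible by seed.
#'
#' @param set an observation set (any data.frame with >= 10 rows).
#' @param test_fraction fraction held out, in (0, 1).
#' @param seed integer seed.
#' @return list with `train`, `test` (data.frames) and `train_idx`,
#'   `test_idx`.
#' @export
split_holdout <- function(set, test_fraction = 0.10, seed = 1L) {
  n <- nrow(set)
  if (n < 10L) stop("need at least 10 observations to split")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  n_test <- max(1L, round(n * test_fraction))
  test_idx <- sort(with_seed(seed, sample.int(n, n_test)))
  train_idx <- setdiff(seq_len(n), test_idx)
  list(train = set[train_idx, , drop = FALSE],
       test = set[test_idx, , drop = FALSE],
       train_idx = train_idx, test_idx = test_idx)
}

# Data-driven log10 hyperparameter bounds: length scales between the median
# nearest-neighbour spacing and the domain size, variances between 1e-6 and
# 10 times the label variance.
.hyper_bounds <- function(X, z) {
  dom <- pmax(apply(X, 2L, function(v) diff(range(v))), 1e-6)
  n <- nrow(X)
  sub <- if (n > 500L) X[seq(1L, n, length.out = 500L), , drop = FALSE] else X
  dmin <- stats::median(vapply(seq_len(nrow(sub)), function(i) {
    d2 <- rowSums(sweep(sub, 2L, sub[i, ], "-")^2)
    sqrt(min(d2[-i]))
  }, 0))
  dmin <- max(dmin, min(dom) * 1e-3)
  vz <- max(stats::var(z), 1e-12)
  list(lower = log10(c(dmin, dmin, 1e-6 * vz, 1e-6 * vz)),
       upper = log10(c(dom[1L], dom[2L], 10 * vz, 10 * vz)))
}

#' Optimize GP hyperparameters by EI Bayesian search
#'
#' Minimizes the negative log marginal likelihood of the anisotropic
#' squared-exponential (or Matern 5/2) GP over log-scaled bounds
#' (length scale per axis, signal variance, noise variance) using
#' [bayes_opt()]'s expected-improvement acquisition, followed by a local
#' Nelder-Mead polish of the incumbent. For cost control the likelihood is
#' evaluated on a seeded subsample of at most `max_train` observations.
#'
#' @param train training observation set (`x_um`, `y_um`, `z`).
#' @param n_iterations EI iterations after the initial design.
#' @param seed integer seed.
#' @param kernel `"se"` or `"matern52"`.
#' @param max_train likelihood-evaluation subsample cap.
#' @return a `gp_hyperparameters` list: `length_scales`, `signal_var`,
#'   `noise_var`, `kernel`, `trace`, `bounds`.
#' @export
optimize_hyperparameters <- function(train, n_iterations = 20L, seed = 1L,
                                     kernel = "se", max_train = 400L) {
  X <- as.matrix(train[, c("x_um", "y_um")])
  z <- train$z
  if (nrow(unique(X)) < 2L) stop("training set degenerate: < 2 distinct positions")
  if (stats::sd(z) == 0) {
    warning("all labels identical: returning a degenerate noise-only model")
    return(structure(list(length_scales = apply(X, 2L, function(v)
      max(diff(range(v)), 1)), signal_var = 1e-12, noise_var = 1e-12,
      kernel = kernel, trace = NULL, bounds = NULL),
      class = "gp_hyperparameters"))
  }
  if (nrow(X) > max_train) {
    idx <- with_seed(sub_seed(seed, "subsample"),
                     sort(sample.int(nrow(X), max_train)))
    X <- X[idx, , drop = FALSE]; z <- z[idx]
  }
  b <- .hyper_bounds(X, z)
  obj <- function(p) {
    p <- 10^p
    gp_nlml(X, z, length_scales = p[1:2], signal_var = p[3L],
            noise_var = p[4L], kernel = kernel)
  }
  vz <- stats::var(z)
  dom <- apply(X, 2L, function(v) diff(range(v)))
  x0 <- log10(c(0.15 * dom[1L], 0.15 * dom[2L], vz, 0.1 * vz))
  opt <- bayes_opt(obj, b$lower, b$upper, n_init = 8L,
                   n_iter = n_iterations, seed = sub_seed(seed, "bo"),
                   x0 = matrix(x0, 1L))
  # local polish of the incumbent on the same objective
  pol <- stats::optim(opt$par, function(p)
    obj(pmin(pmax(p, b$lower), b$upper)),
    method = "Nelder-Mead", control = list(maxit = 80L))
  best <- if (pol$value < opt$value)
    pmin(pmax(pol$par, b$lower), b$upper) else opt$par
  p <- 10^best
  structure(list(length_scales = unname(p[1:2]), signal_var = unname(p[3L]),
                 noise_var = unname(p[4L]), kernel = kernel,
                 trace = opt$trace, bounds = b),
            class = "gp_hyperparameters")
}

#' Fit the behavior surface by exact GP conditioning
#'
#' @param train training observation set.
#' @param hyperparameters a `gp_hyperparameters` (from
#'   [optimize_hyperparameters()]) or a list with `length_scales`,
#'   `signal_var`, `noise_var`, `kernel`.
#' @param max_train conditioning-set cap (seeded subsample above it).
#' @param seed seed for the subsample draw.
#' @return a `fitted_surface`: the underlying [gp_fit()] plus metadata.
#' @export
fit_surface <- function(train, hyperparameters, max_train = 1000L,
                        seed = 1L) {
  X <- as.matrix(train[, c("x_um", "y_um")])
  z <- train$z
  idx <- seq_len(nrow(X))
  if (nrow(X) > max_train)
    idx <- with_seed(sub_seed(seed, "fit-subsample"),
                     sort(sample.int(nrow(X), max_train)))
  h <- hyperparameters
  sv <- max(h$signal_var, 1e-12)
  fit <- gp_fit(X[idx, , drop = FALSE], z[idx],
                length_scales = h$length_scales, signal_var = sv,
                noise_var = max(h$noise_var, 1e-12 * sv),
                kernel = h$kernel %||% "se")
  structure(list(gp = fit, hyperparameters = h, train_idx = idx,
                 n_train = length(idx),
                 bbox = list(x = range(train$x_um), y = range(train$y_um)),
                 behavior_name = attr(train, "behavior_name"),
                 cell_type = attr(train, "cell_type")),
            class = "fitted_surface")
}

#' @export
print.fitted_surface <- function(x, ...) {
  h <- x$hyperparameters
  cat(sprintf(
    "Fitted GP surface (%s kernel): %d training points\n  length scales (%.3g, %.3g) um, signal var %.3g, noise var %.3g\n",
    h$kernel %||% "se", x$n_train, h$length_scales[1L], h$length_scales[2L],
    h$signal_var, h$noise_var))
  invisible(x)
}

# Factor `total` into nx * ny as close as possible to the aspect ratio.
.grid_factorization <- function(total, aspect) {
  divs <- which(total %% seq_len(total) == 0)
  ny <- total / divs
  mis <- abs(log((divs / ny) / aspect))
  c(nx = divs[which.min(mis)], ny = ny[which.min(mis)])
}

#' Predict the dense behavior grid (the cell map)
#'
#' Evaluates posterior mean and predictive sd on a rectangular grid of
#' exactly `total_points` points spanning the observation bounding box.
#' This is the false-null correction step: behavior values are filled in
#' over cell-free regions where no observation exists.
#'
#' @param surface a [fit_surface()] result.
#' @param bbox list with `x`, `y` ranges; default the training bounding
#'   box.
#' @param total_points total grid size (default 250000, i.e. 500 x 500 on a
#'   square box; non-square boxes use the nearest aspect-preserving
#'   factorization of exactly `total_points`).
#' @return a `behavior_grid`: list with vectors `x_um`, `y_um`, matrices
#'   `z_mean`, `z_sd` (`length(x_um)` by `length(y_um)`), and `n_points`.
#' @export
predict_grid <- function(surface, bbox = NULL, total_points = 250000L) {
  stopifnot(inherits(surface, "fitted_surface"), total_points >= 4)
  if (is.null(bbox)) bbox <- surface$bbox
  aspect <- max(diff(bbox$x), 1e-9) / max(diff(bbox$y), 1e-9)
  f <- .grid_factorization(as.integer(total_points), aspect)
  xs <- seq(bbox$x[1L], bbox$x[2L], length.out = f["nx"])
  ys <- seq(bbox$y[1L], bbox$y[2L], length.out = f["ny"])
  Xnew <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  pr <- gp_predict(surface$gp, Xnew)
  structure(list(x_um = xs, y_um = ys,
                 z_mean = matrix(pr$mean, length(xs), length(ys)),
                 z_sd = matrix(pr$sd, length(xs), length(ys)),
                 n_points = length(xs) * length(ys),
                 behavior_name = surface$behavior_name,
                 cell_type = surface$cell_type),
            class = "behavior_grid")
}

#' Hold-out prediction error of a fitted surface
#'
#' @param surface a [fit_surface()] result.
#' @param test held-out observation set.
#' @return list with `rmse` and `r2` (coefficient of determination; at or
#'   below 0 when the surface predicts no better than the test mean).
#' @export
holdout_error <- function(surface, test) {
  stopifnot(nrow(test) > 0L)
  pr <- gp_predict(surface$gp, as.matrix(test[, c("x_um", "y_um")]))
  resid <- test$z - pr$mean
  sst <- sum((test$z - mean(test$z))^2)
  list(rmse = sqrt(mean(resid^2)),
       r2 = if (sst > 0) 1 - sum(resid^2) / sst else NA_real_)
}

#' Marginalize a behavior grid into a feature-size response curve
#'
#' Maps every grid column to its local feature size through the
#' position-size calibration, then averages the predicted behavior over y
#' within log-spaced size bins. This converts the spatial cell map into
#' behavior versus topography feature size.
#'
#' @param grid a [predict_grid()] result.
#' @param calibration a `size_calibration` valid over the grid x-range.
#' @param n_size_bins number of log-spaced bins.
#' @param size_range optional c(min, max) size range for the bins,
#'   micrometres; default the range mapped by the grid.
#' @return a `size_response_curve` data.frame: `bin`, `size_lo_um`,
#'   `size_hi_um`, `size_mid_um` (geometric mid), `mean`, `sd`, `n`.
#' @export
marginalize_to_size_curve <- function(grid, calibration, n_size_bins = 8L,
                                      size_range = NULL) {
  stopifnot(inherits(grid, "behavior_grid"),
            inherits(calibration, "size_calibration"), n_size_bins >= 2L)
  vr <- calibration$valid_range_um
  tol <- 0.05 * diff(vr)
  if (min(grid$x_um) < vr[1L] - tol || max(grid$x_um) > vr[2L] + tol)
    stop("calibration range mismatch: grid x extends beyond the calibrated range")
  sizes <- position_to_feature_size(calibration, grid$x_um, warn = FALSE)
  if (is.null(size_range)) size_range <- range(sizes)
  edges <- exp(seq(log(size_range[1L]), log(size_range[2L]),
                   length.out = n_size_bins + 1L))
  bin <- findInterval(sizes, edges, rightmost.closed = TRUE)
  bin[bin < 1L | bin > n_size_bins] <- NA_integer_
  rows <- lapply(seq_len(n_size_bins), function(k) {
    cols <- which(bin == k)
    z <- if (length(cols)) as.vector(grid$z_mean[cols, ]) else numeric(0)
    data.frame(bin = k, size_lo_um = edges[k], size_hi_um = edges[k + 1L],
               size_mid_um = sqrt(edges[k] * edges[k + 1L]),
               mean = if (length(z)) mean(z) else NA_real_,
               sd = if (length(z) > 1L) stats::sd(z) else 0,
               n = length(z))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("size_response_curve", "data.frame"),
            behavior_name = grid$behavior_name, cell_type = grid$cell_type,
            bin_edges = edges)
}
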