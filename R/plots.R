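#' Heat-map of a behavior grid
#'
#' @param grid a [predict_grid()] result.
#' @param what `"mean"` or `"sd"`.
#' @param ... passed to [graphics::image()].
#' @export
plot_behavior_grid <- function(grid, what = c("mean", "sd"), ...) {
  what <- match.arg(what)
  z <- if (what == "mean") grid$z_mean else grid$z_sd
  graphics::image(grid$x_um, grid$y_um, z,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x (um)", ylab = "y (um)",
                  main = sprintf("%s (%s)", grid$behavior_name %||% "behavior",
                                 what), useRaster = TRUE, ...)
  invisible(grid)
}

#' Radar chart of one or more radar tables
#'
#' One spoke per (behavior, size bin) cell, levels 1..n radially;
#' overlaying several cell types shows the mechanosensitivity contrast.
#'
#' @param tables a `radar_table` or named list of them.
#' @param main plot title.
#' @export
plot_radar <- function(tables, main = "Behavior radar") {
  if (inherits(tables, "radar_table")) tables <- list(tables)
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, function(t)
      attr(t, "cell_type") %||% "type", "")
  t1 <- tables[[1L]]
  n_levels <- attr(t1, "n_levels") %||% 5L
  vals <- lapply(tables, function(t) as.vector(t(unclass(t))))
  k <- length(vals[[1L]])
  ang <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  graphics::plot(NA, xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  for (r in seq_len(n_levels) / n_levels)
    graphics::polygon(r * cos(ang), r * sin(ang), border = "grey80")
  cols <- grDevices::hcl.colors(max(3L, length(vals)), "Dark 3")
  for (i in seq_along(vals)) {
    r <- vals[[i]] / n_levels
    graphics::polygon(r * cos(ang), r * sin(ang), border = cols[i],
                      col = grDevices::adjustcolor(cols[i], 0.15), lwd = 2)
  }
  labs <- paste(rep(rownames(t1), each = ncol(t1)),
                rep(seq_len(ncol(t1)), nrow(t1)), sep = ".")
  graphics::text(1.12 * cos(ang), 1.12 * sin(ang), labs, cex = 0.5)
  graphics::legend("topright", legend = names(tables), col = cols[seq_along(vals)],
                   lwd = 2, bty = "n", cex = 0.7)
  invisible(tables)
}

#' Period and linewidth of a topography profile
#'
#' @param profile a `topography_profile`.
#' @export
plot_topography_profile <- function(profile) {
  graphics::plot(profile$position_um / 1000, profile$period_um, log = "y",
                 type = "l", lwd = 2, xlab = "position (mm)",
                 ylab = "feature size (um)",
                 main = "Gradient topography profile")
  graphics::lines(profile$position_um / 1000, profile$linewidth_um,
                  col = "grey50")
  graphics::legend("topright", c("period", "linewidth"),
                   col = c("black", "grey50"), lwd = c(2, 1), bty = "n")
  invisible(profile)
}
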