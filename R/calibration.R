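#' Fit the position-to-feature-size calibration
#'
#' Least-squares fit of `log(period)` against substrate position. On the
#' gradient array the log feature size is nearly linear in position, which
#' is what makes positions trackable proxies for local feature size.
#'
#' @param profile a `topography_profile`.
#' @param central_fraction fraction of the position range, centred, used for
#'   the fit (1 = all samples; 0.8 drops the outer 10% on each side where
#'   the interference geometry departs from log-linearity).
#' @return a `size_calibration`: list with `intercept` (log-um), `slope`
#'   (per um), `r_squared`, `valid_range_um`, `n_used`.
#' @export
fit_size_calibration <- function(profile, central_fraction = 1) {
  stopifnot(inherits(profile, "topography_profile"),
            central_fraction > 0, central_fraction <= 1)
  pos <- profile$position_um
  per <- profile$period_um
  if (length(pos) < 3L) stop("need at least 3 profile samples")
  bad <- which(!is.finite(per) | per <= 0)
  if (length(bad))
    stop(sprintf("non-positive period at profile sample %d (x = %g um)",
                 bad[1L], pos[bad[1L]]))
  if (central_fraction < 1) {
    lo <- stats::quantile(pos, (1 - central_fraction) / 2)
    hi <- stats::quantile(pos, 1 - (1 - central_fraction) / 2)
    keep <- pos >= lo & pos <= hi
    pos <- pos[keep]; per <- per[keep]
  }
  y <- log(per)
  if (stats::sd(y) == 0) {
    cal <- list(intercept = y[1L], slope = 0, r_squared = 0,
                valid_range_um = range(pos), n_used = length(pos))
    class(cal) <- "size_calibration"
    return(cal)
  }
  fit <- stats::lm.fit(cbind(1, pos), y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  cal <- list(intercept = unname(fit$coefficients[1L]),
              slope = unname(fit$coefficients[2L]),
              r_squared = r2,
              valid_range_um = range(pos),
              n_used = length(pos))
  class(cal) <- "size_calibration"
  cal
}

#' @export
print.size_calibration <- function(x, ...) {
  cat(sprintf(
    "Size calibration: log(period) = %.4g %+.4g * x,  R^2 = %.4f\n",
    x$intercept, x$slope, x$r_squared))
  cat(sprintf("  valid for x in [%g, %g] um (%d samples)\n",
              x$valid_range_um[1L], x$valid_range_um[2L], x$n_used))
  invisible(x)
}

#' Predicted local feature size at a substrate position
#'
#' @param calibration a `size_calibration`.
#' @param x_um positions in micrometres.
#' @param warn warn when extrapolating outside the fitted range.
#' @return feature sizes (periods) in micrometres.
#' @export
position_to_feature_size <- function(calibration, x_um, warn = TRUE) {
  stopifnot(inherits(calibration, "size_calibration"))
  out <- x_um < calibration$valid_range_um[1L] |
         x_um > calibration$valid_range_um[2L]
  if (warn && any(out))
    warning(sprintf("%d position(s) outside the calibrated range: extrapolating",
                    sum(out)))
  exp(calibration$intercept + calibration$slope * x_um)
}

#' Inverse calibration query: position at which a feature size occurs
#'
#' @param calibration a `size_calibration` with non-zero slope.
#' @param size_um feature sizes in micrometres.
#' @return positions in micrometres.
#' @export
feature_size_to_position <- function(calibration, size_um) {
  stopifnot(inherits(calibration, "size_calibration"))
  if (calibration$slope == 0)
    stop("calibration slope is zero: size does not identify a position")
  (log(size_um) - calibration$intercept) / calibration$slope
}
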