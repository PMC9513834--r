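#' Structure-tensor orientation histogram of an image
#'
#' Local orientations from the smoothed image structure tensor, weighted by
#' coherence times gradient energy, binned on `[-90, 90)` degrees (axial
#' data: an orientation and its 180-degree rotation are the same). The
#' reported structure orientation is perpendicular to the dominant gradient
#' direction, i.e. along stripes/fibers. Used for automatic quantification
#' of axon and fiber alignment.
#'
#' @param image numeric matrix (first index x).
#' @param bin_width_deg histogram bin width, degrees.
#' @param sigma_grad Gaussian pre-smoothing before gradients, pixels.
#' @param sigma_tensor Gaussian smoothing of the tensor components, pixels.
#' @return an `orientation_histogram`: list with `angle_deg` (bin centres),
#'   `weight` (normalized), `dominant_angle_deg`, `alignment_score` in
#'   `[0, 1]` and `degenerate` flag.
#' @export
orientation_histogram <- function(image, bin_width_deg = 2,
                                  sigma_grad = 1, sigma_tensor = 2) {
  stopifnot(is.matrix(image))
  if (min(dim(image)) < 8L)
    stop("image smaller than the gradient window")
  sm <- as.matrix(EBImage::gblur(EBImage::Image(image), sigma = sigma_grad)@.Data)
  nx <- nrow(sm); ny <- ncol(sm)
  gx <- matrix(0, nx, ny); gy <- matrix(0, nx, ny)
  gx[2:(nx - 1), ] <- (sm[3:nx, ] - sm[1:(nx - 2), ]) / 2
  gy[, 2:(ny - 1)] <- (sm[, 3:ny] - sm[, 1:(ny - 2)]) / 2
  blur <- function(m) as.matrix(EBImage::gblur(EBImage::Image(m),
                                               sigma = sigma_tensor)@.Data)
  jxx <- blur(gx * gx); jyy <- blur(gy * gy); jxy <- blur(gx * gy)
  # trim the border where gradients/smoothing are truncated
  tb <- ceiling(2 * sigma_tensor) + 1L
  sel <- cbind(rep((tb + 1L):(nx - tb), ny - 2L * tb),
               rep((tb + 1L):(ny - tb), each = nx - 2L * tb))
  jxx <- jxx[sel]; jyy <- jyy[sel]; jxy <- jxy[sel]
  energy <- jxx + jyy
  bins <- seq(-90, 90, by = bin_width_deg)
  centres <- (bins[-1L] + bins[-length(bins)]) / 2
  if (max(energy) <= 0) {
    return(structure(list(angle_deg = centres,
                          weight = rep(1 / length(centres), length(centres)),
                          dominant_angle_deg = NA_real_,
                          alignment_score = 0, degenerate = TRUE),
                     class = "orientation_histogram"))
  }
  coherence <- sqrt((jxx - jyy)^2 + 4 * jxy^2) / (energy + 1e-12)
  w <- coherence * energy
  # gradient-dominant direction; structures run perpendicular to it
  grad_ang <- 0.5 * atan2(2 * jxy, jxx - jyy)
  ori <- grad_ang * 180 / pi + 90
  ori <- ((ori + 90) %% 180) - 90
  h <- stats::aggregate(w, list(bin = findInterval(ori, bins,
                                                   rightmost.closed = TRUE)),
                        sum)
  weight <- numeric(length(centres))
  idx <- pmin(pmax(h$bin, 1L), length(centres))
  weight[idx] <- weight[idx] + h$x
  weight <- weight / sum(weight)
  # axial resultant on doubled angles
  z <- sum(w * exp(2i * ori * pi / 180)) / sum(w)
  score <- Mod(z)
  peak <- centres[which.max(weight)]
  near <- abs(((ori - peak + 90) %% 180) - 90) <= 10
  zn <- sum(w[near] * exp(2i * ori[near] * pi / 180))
  dom <- Arg(zn) / 2 * 180 / pi
  dom <- ((dom + 90) %% 180) - 90
  structure(list(angle_deg = centres, weight = weight,
                 dominant_angle_deg = dom, alignment_score = score,
                 degenerate = FALSE),
            class = "orientation_histogram")
}

#' @export
print.orientation_histogram <- function(x, ...) {
  cat(sprintf("Orientation histogram: dominant %.1f deg, alignment score %.3f%s\n",
              x$dominant_angle_deg, x$alignment_score,
              if (isTRUE(x$degenerate)) " (degenerate: no gradient)" else ""))
  invisible(x)
}

# Zhang-Suen binary thinning; vectorized over the full matrix per pass.
.skeletonize <- function(mask) {
  img <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  img[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (mask > 0) * 1L
  nx <- nrow(img); ny <- ncol(img)
  shift <- function(m, dx, dy) {
    out <- matrix(0L, nx, ny)
    xs <- (1L + max(0, dx)):(nx + min(0, dx))
    ys <- (1L + max(0, dy)):(ny + min(0, dy))
    out[xs, ys] <- m[xs - dx, ys - dy]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- shift(img, 0, -1); p3 <- shift(img, 1, -1); p4 <- shift(img, 1, 0)
      p5 <- shift(img, 1, 1);  p6 <- shift(img, 0, 1);  p7 <- shift(img, -1, 1)
      p8 <- shift(img, -1, 0); p9 <- shift(img, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      A <- matrix(0L, nx, ny)
      for (k in 1:8) A <- A + (seqs[[k]] == 0L & seqs[[k + 1L]] == 1L)
      if (pass == 1L) {
        cond <- img == 1L & B >= 2L & B <= 6L & A == 1L &
          (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- img == 1L & B >= 2L & B <= 6L & A == 1L &
          (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) { img[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  img[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L), drop = FALSE]
}

# Path length of a skeleton in pixels: each 4-neighbour link counts 1, each
# diagonal link sqrt(2); links shared by two pixels are counted once.
.skeleton_length_px <- function(skel) {
  nx <- nrow(skel); ny <- ncol(skel)
  orth <- sum(skel[-nx, ] & skel[-1L, ]) + sum(skel[, -ny] & skel[, -1L])
  diag1 <- sum(skel[-nx, -ny] & skel[-1L, -1L])
  diag2 <- sum(skel[-1L, -ny] & skel[-nx, -1L])
  orth + sqrt(2) * (diag1 + diag2)
}

#' Skeleton-based neurite length per connected component
#'
#' Thresholds (if needed), labels 8-connected components, thins each to a
#' one-pixel skeleton and sums the skeleton path length (orthogonal steps
#' count one pixel, diagonal steps sqrt(2)). An automated substitute for
#' manual axon tracing. Components whose skeletons contain junction pixels
#' (entangled/crossing axons) are excluded when `exclude_entangled` is
#' `TRUE`; components whose x-extent spans feature sizes differing by more
#' than `max_size_ratio` (crossing topography regimes) are excluded when a
#' topography profile is supplied.
#'
#' @param image numeric or logical matrix (first index x).
#' @param pixel_size_um pixel pitch.
#' @param threshold numeric threshold for grayscale input; `NULL` uses Otsu.
#' @param min_length_px drop skeletons shorter than this many pixels.
#' @param exclude_entangled drop components with skeleton junctions.
#' @param topography optional `topography_profile` for the size-regime
#'   filter (image x assumed aligned with profile positions).
#' @param max_size_ratio maximum allowed feature-size ratio across one
#'   component's x-extent.
#' @return data.frame `id`, `length_um`, `n_px`, `x_min_um`, `x_max_um`.
#' @export
neurite_lengths <- function(image, pixel_size_um = NULL, threshold = NULL,
                            min_length_px = 5, exclude_entangled = TRUE,
                            topography = NULL, max_size_ratio = 2) {
  stopifnot(is.matrix(image))
  if (is.null(pixel_size_um))
    pixel_size_um <- attr(image, "pixel_size_um") %||% 0.65
  if (is.logical(image)) mask <- image else {
    if (max(image) <= min(image)) mask <- image > Inf
    else {
      thr <- if (is.null(threshold))
        EBImage::otsu(EBImage::Image(pmin(pmax(image, 0), 1))) else threshold
      mask <- image > thr
    }
  }
  empty <- data.frame(id = integer(), length_um = numeric(), n_px = integer(),
                      x_min_um = numeric(), x_max_um = numeric())
  if (!any(mask)) return(empty)
  lab <- .label8(mask)
  rows <- list()
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < min_length_px) next
    x0 <- min(idx[, 1L]); x1 <- max(idx[, 1L])
    y0 <- min(idx[, 2L]); y1 <- max(idx[, 2L])
    sub <- matrix(0L, x1 - x0 + 1L, y1 - y0 + 1L)
    sub[cbind(idx[, 1L] - x0 + 1L, idx[, 2L] - y0 + 1L)] <- 1L
    skel <- .skeletonize(sub)
    npx <- sum(skel)
    if (npx < min_length_px) next
    if (exclude_entangled) {
      nsx <- nrow(skel); nsy <- ncol(skel)
      nb <- matrix(0L, nsx, nsy)
      for (dx in -1:1) for (dy in -1:1) if (dx || dy) {
        xs <- (1L + max(0L, dx)):(nsx + min(0L, dx))
        ys <- (1L + max(0L, dy)):(nsy + min(0L, dy))
        if (xs[1L] > xs[length(xs)] || ys[1L] > ys[length(ys)]) next
        sh <- matrix(0L, nsx, nsy)
        sh[xs, ys] <- skel[xs - dx, ys - dy, drop = FALSE]
        nb <- nb + sh
      }
      if (any(skel == 1L & nb >= 3L)) next     # junction: entangled
    }
    xmin_um <- (x0 - 0.5) * pixel_size_um
    xmax_um <- (x1 - 0.5) * pixel_size_um
    if (!is.null(topography)) {
      s <- stats::approx(topography$position_um, topography$period_um,
                         xout = c(xmin_um, xmax_um), rule = 2, ties = mean)$y
      if (max(s) / min(s) > max_size_ratio) next  # spans size regimes
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = k, length_um = .skeleton_length_px(skel) * pixel_size_um,
      n_px = npx, x_min_um = xmin_um, x_max_um = xmax_um)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$id <- seq_len(nrow(out))
  out
}
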