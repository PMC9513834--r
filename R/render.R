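# Image convention used throughout the package: numeric matrices in [0, 1]
# with the FIRST index along x (image width) and the second along y, the
# same layout EBImage uses. Orientation angles are measured in degrees from
# the +x axis towards the +y axis, reported on [-90, 90).

#' Render a fluorescence-like image of a synthetic scene
#'
#' Each cell becomes an anisotropic Gaussian blob whose half-maximum
#' footprint matches the cell's area, eccentricity and orientation. For
#' intensity channels the blob brightness is proportional to the cell's
#' behavior value; the nuclear stain (`dapi`) has constant brightness.
#' A flat background (5% of full scale) and shot-like noise (standard
#' deviation growing with the square root of signal) are added.
#'
#' @param scene a `synthetic_scene` from [make_scene()].
#' @param channel `"actin"`, `"tuj1_map2"`, `"cfse"` or `"dapi"`.
#' @param pixel_size_um pixel pitch in micrometres (default 0.65).
#' @param background background level, fraction of full scale.
#' @param noise_scale shot-noise scale (0 disables noise).
#' @param seed seed for the noise draw.
#' @return numeric matrix in `[0, 1]`, attribute `pixel_size_um`.
#' @export
render_fluorescence_image <- function(scene,
                                      channel = c("actin", "tuj1_map2",
                                                  "cfse", "dapi"),
                                      pixel_size_um = 0.65,
                                      background = 0.05,
                                      noise_scale = 0.01,
                                      seed = 1L) {
  channel <- match.arg(channel)
  stopifnot(inherits(scene, "synthetic_scene"), pixel_size_um > 0)
  width_um <- diff(range(scene$topography$position_um))
  nx <- max(8L, ceiling(width_um / pixel_size_um))
  ny <- max(8L, ceiling(scene$height_um / pixel_size_um))
  img <- matrix(0, nx, ny)
  cells <- scene$cells
  x0 <- min(scene$topography$position_um)
  if (nrow(cells)) {
    zr <- range(cells$z)
    rel <- if (diff(zr) > 0) (cells$z - zr[1L]) / diff(zr) else rep(1, nrow(cells))
    amp <- switch(channel,
                  dapi = rep(0.6, nrow(cells)),
                  0.25 + 0.65 * rel)
    for (i in seq_len(nrow(cells))) {
      cx <- (cells$x_um[i] - x0) / pixel_size_um + 0.5
      cy <- cells$y_um[i] / pixel_size_um + 0.5
      A_px <- cells$area_um2[i] / pixel_size_um^2
      ecc <- min(cells$eccentricity[i], 0.995)
      ab_ratio <- 1 / sqrt(1 - ecc^2)            # half-axis ratio a/b
      # half-maximum footprint pi*a*b = A_px
      b <- sqrt(A_px / (pi * ab_ratio))
      a <- ab_ratio * b
      s <- sqrt(2 * log(2))                       # half-max radius in sigmas
      sa <- a / s; sb <- b / s
      th <- cells$orientation_deg[i] * pi / 180
      win <- ceiling(4 * max(sa, sb))
      ix <- max(1L, floor(cx - win)):min(nx, ceiling(cx + win))
      iy <- max(1L, floor(cy - win)):min(ny, ceiling(cy + win))
      if (!length(ix) || !length(iy)) next
      dx <- outer(ix - cx, rep(1, length(iy)))
      dy <- outer(rep(1, length(ix)), iy - cy)
      ra <- dx * cos(th) + dy * sin(th)
      rb <- -dx * sin(th) + dy * cos(th)
      img[ix, iy] <- img[ix, iy] +
        amp[i] * exp(-0.5 * ((ra / sa)^2 + (rb / sb)^2))
    }
  }
  img <- img + background
  if (noise_scale > 0)
    img <- img + with_seed(seed, matrix(stats::rnorm(length(img), 0, 1),
                                        nx, ny)) *
      noise_scale * sqrt(pmax(img, 0))
  img[] <- pmin(1, pmax(0, img))
  attr(img, "pixel_size_um") <- pixel_size_um
  img
}

#' Render an aligned-fiber texture image
#'
#' Parallel Gaussian ridges ("fibers") at a given orientation with
#' Poisson-jittered spacing, used to exercise the orientation analysis the
#' way aligned electrospun nanofiber images do. A non-positive
#' `fiber_diameter_um` degenerates to an isotropic noise image.
#'
#' @param orientation_deg fiber direction, degrees from the +x axis on
#'   `[-90, 90)`.
#' @param fiber_diameter_um fiber width (full width at half maximum),
#'   micrometres.
#' @param pixel_size_um pixel pitch, micrometres.
#' @param seed seed for spacing jitter and noise.
#' @param size_px image side length in pixels.
#' @param mean_spacing_um mean centre-to-centre fiber spacing; default
#'   2.5 fiber diameters.
#' @param background,noise_sd background level and additive noise sd.
#' @return numeric matrix in `[0, 1]`, attribute `pixel_size_um`.
#' @export
render_fiber_image <- function(orientation_deg, fiber_diameter_um = 1,
                               pixel_size_um = 0.65, seed = 1L,
                               size_px = 256L, mean_spacing_um = NULL,
                               background = 0.05, noise_sd = 0.02) {
  stopifnot(pixel_size_um > 0, size_px >= 16L)
  if (fiber_diameter_um <= 0) {
    img <- with_seed(seed, matrix(stats::runif(size_px^2), size_px, size_px))
    attr(img, "pixel_size_um") <- pixel_size_um
    attr(img, "degenerate") <- TRUE
    return(img)
  }
  if (is.null(mean_spacing_um)) mean_spacing_um <- 2.5 * fiber_diameter_um
  th <- orientation_deg * pi / 180
  xs <- (seq_len(size_px) - 0.5) * pixel_size_um
  # perpendicular coordinate of every pixel
  v <- outer(xs * (-sin(th)), rep(1, size_px)) +
       outer(rep(1, size_px), xs * cos(th))
  vr <- range(v)
  img <- with_seed(seed, {
    gaps <- stats::rexp(ceiling(3 * diff(vr) / mean_spacing_um) + 10L,
                        rate = 1 / mean_spacing_um)
    centers <- vr[1L] - mean_spacing_um + cumsum(gaps)
    centers <- centers[centers < vr[2L] + mean_spacing_um]
    sig <- fiber_diameter_um / (2 * sqrt(2 * log(2)))
    out <- matrix(0, size_px, size_px)
    for (cc in centers)
      out <- out + exp(-0.5 * ((v - cc) / sig)^2)
    out <- background + 0.8 * out / max(out)
    out + stats::rnorm(length(out), 0, noise_sd)
  })
  img[] <- pmin(1, pmax(0, img))
  attr(img, "pixel_size_um") <- pixel_size_um
  img
}

#' Write an image matrix to TIFF or PNG
#'
#' @param img numeric matrix in `[0, 1]`, first index x.
#' @param path output path ending in `.tif`, `.tiff` or `.png`; 16-bit TIFF.
#' @export
write_image <- function(img, path) {
  m <- t(img)[, , drop = TRUE]            # row-major (y, x) for writers
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to write TIFF files")
    tiff::writeTIFF(m, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the 'png' package is required to write PNG files")
    png::writePNG(m, path)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' Read a TIFF or PNG image into the package's matrix convention
#'
#' @param path image path.
#' @param pixel_size_um pixel pitch recorded on the returned matrix.
#' @return numeric matrix in `[0, 1]`, first index x.
#' @export
read_image <- function(path, pixel_size_um = 0.65) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF files")
    tiff::readTIFF(path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the 'png' package is required to read PNG files")
    png::readPNG(path)
  } else stop("unsupported image format: ", ext)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  img <- t(m)
  attr(img, "pixel_size_um") <- pixel_size_um
  img
}
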