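#' Subtract the smooth illumination background from an image
#'
#' Estimates the background by grayscale morphological opening (erosion then
#' dilation with a disc, the rolling-ball-equivalent used for fluorescent
#' illumination flattening) and subtracts it, clipping at zero. Features
#' smaller than the disc survive; smooth gradients are removed.
#'
#' @param image numeric matrix (first index x).
#' @param radius_px structuring-element radius in pixels.
#' @return background-subtracted matrix, same attributes.
#' @export
subtract_background <- function(image, radius_px = 25) {
  stopifnot(is.matrix(image), radius_px > 0)
  if (2 * radius_px + 1 >= min(dim(image)))
    stop("background radius must be smaller than the image")
  brush <- EBImage::makeBrush(2 * as.integer(radius_px) + 1L, shape = "disc")
  bg <- EBImage::opening(EBImage::Image(image), brush)
  out <- pmax(image - as.matrix(bg@.Data), 0)
  attributes(out) <- attributes(image)
  out
}

# 8-connectivity labelling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged with a union-find over the label graph.
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- as.matrix(lab@.Data)
  nlab <- max(lab)
  if (nlab < 2L) return(lab)
  nx <- nrow(lab); ny <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nx, -ny]), as.vector(lab[-1L, -1L])),
    cbind(as.vector(lab[-1L, -ny]), as.vector(lab[-nx, -1L])))
  pairs <- pairs[pairs[, 1L] > 0 & pairs[, 2L] > 0 &
                 pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1L]); b <- find(pairs[k, 2L])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nlab), find, 0L)
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Detect fluorescent objects and measure them
#'
#' Global threshold (Otsu by default), 8-connected components, and an
#' inclusive pixel-area filter (default 8 to 80 px, the screening
#' segmentation window at 0.65 um per pixel). Each retained object is
#' measured: centroid (micrometres), area, perimeter, circularity
#' `4*pi*A/P^2`, second-moment ellipse axes and mean intensity.
#'
#' @param image numeric matrix in `[0, 1]` (first index x).
#' @param min_area_px,max_area_px inclusive pixel-area filter bounds.
#' @param pixel_size_um pixel pitch (defaults to the image attribute or
#'   0.65).
#' @param threshold numeric global threshold; `NULL` uses Otsu.
#' @return data.frame of `segmented_objects` (one row per object; empty for
#'   a blank image) with the label matrix as attribute `labels`.
#' @export
detect_objects <- function(image, min_area_px = 8, max_area_px = 80,
                           pixel_size_um = NULL, threshold = NULL) {
  stopifnot(is.matrix(image), min_area_px < max_area_px)
  if (is.null(pixel_size_um))
    pixel_size_um <- attr(image, "pixel_size_um") %||% 0.65
  empty <- data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                      area_px = numeric(), area_um2 = numeric(),
                      perimeter_px = numeric(), circularity = numeric(),
                      major_axis_um = numeric(), minor_axis_um = numeric(),
                      eccentricity = numeric(), theta_deg = numeric(),
                      mean_intensity = numeric())
  if (max(image) <= min(image)) return(structure(empty, labels = NULL))
  thr <- if (is.null(threshold))
    EBImage::otsu(EBImage::Image(pmin(pmax(image, 0), 1))) else threshold
  mask <- image > thr
  if (!any(mask)) return(structure(empty, labels = NULL))
  lab <- .label8(mask)
  shp <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab, image)
  bas <- EBImage::computeFeatures.basic(lab, image)
  if (is.null(dim(shp))) { shp <- t(shp); mom <- t(mom); bas <- t(bas) }
  area <- shp[, "s.area"]
  keep <- which(area >= min_area_px & area <= max_area_px)
  perim <- pmax(shp[keep, "s.perimeter"], 1)
  circ <- pmin(4 * pi * area[keep] / perim^2, 1)
  major <- mom[keep, "m.majoraxis"]
  ecc <- mom[keep, "m.eccentricity"]
  minor <- major * sqrt(pmax(1 - ecc^2, 0))
  out <- data.frame(
    id = seq_along(keep),
    x_um = (mom[keep, "m.cx"] - 0.5) * pixel_size_um,
    y_um = (mom[keep, "m.cy"] - 0.5) * pixel_size_um,
    area_px = area[keep],
    area_um2 = area[keep] * pixel_size_um^2,
    perimeter_px = perim,
    circularity = circ,
    major_axis_um = major * pixel_size_um,
    minor_axis_um = minor * pixel_size_um,
    eccentricity = ecc,
    theta_deg = mom[keep, "m.theta"] * 180 / pi,
    mean_intensity = bas[keep, "b.mean"])
  rownames(out) <- NULL
  lab_keep <- lab
  lab_keep[!(lab %in% keep)] <- 0L
  lab_keep[lab_keep > 0] <- match(lab_keep[lab_keep > 0], keep)
  structure(out, labels = lab_keep, pixel_size_um = pixel_size_um)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shape measurements of a single object mask
#'
#' Circularity is `4*pi*A/P^2` (1 for a disc, small for elongated shapes),
#' clipped to `[0, 1]` since digital perimeters of tiny masks (a single
#' pixel has perimeter 1 by the boundary-pixel-count convention) can push
#' the raw value above 1. Polarization is defined as `1 - circularity`.
#'
#' @param mask logical or 0/1 matrix containing one object.
#' @return list with `area_px`, `perimeter_px`, `circularity`,
#'   `polarization`, `major_axis_px`, `minor_axis_px`.
#' @export
measure_shape <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- (mask > 0) * 1L
  if (!any(mask > 0)) stop("empty mask")
  lab <- EBImage::Image(mask)
  shp <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab)
  if (is.null(dim(shp))) { shp <- t(shp); mom <- t(mom) }
  area <- shp[1L, "s.area"]
  perim <- max(shp[1L, "s.perimeter"], 1)
  circ <- min(4 * pi * area / perim^2, 1)
  major <- mom[1L, "m.majoraxis"]
  minor <- major * sqrt(max(1 - mom[1L, "m.eccentricity"]^2, 0))
  list(area_px = unname(area), perimeter_px = unname(perim),
       circularity = unname(circ), polarization = unname(1 - circ),
       major_axis_px = unname(major), minor_axis_px = unname(max(minor, 1)))
}

#' Tile an image into mean-intensity observations
#'
#' Pixelizes the image into `n_tiles` rectangular tiles (48 to 576, the
#' screening pixelization range), chosen as the factorization closest to
#' the image aspect ratio, and returns the mean intensity and centre of
#' each tile. Tile boundaries partition the image exactly.
#'
#' @param image numeric matrix (first index x), ideally
#'   background-subtracted.
#' @param n_tiles total number of tiles, in `[48, 576]`.
#' @param pixel_size_um pixel pitch.
#' @return data.frame `tile`, `x_um`, `y_um`, `mean_intensity`,
#'   `tile_w_px`, `tile_h_px`.
#' @export
pixelize_intensity <- function(image, n_tiles = 100L, pixel_size_um = NULL) {
  stopifnot(is.matrix(image))
  if (n_tiles < 48 || n_tiles > 576)
    stop("n_tiles must be between 48 and 576")
  if (is.null(pixel_size_um))
    pixel_size_um <- attr(image, "pixel_size_um") %||% 0.65
  nx <- nrow(image); ny <- ncol(image)
  divs <- which(n_tiles %% seq_len(n_tiles) == 0)
  cand <- data.frame(tx = divs, ty = n_tiles / divs)
  mis <- abs(log((cand$tx / cand$ty) / (nx / ny)))
  best <- cand[which.min(mis), ]
  if (min(mis) > log(2))
    stop("n_tiles cannot be factorized within 2x of the image aspect ratio")
  bx <- round(seq(0, nx, length.out = best$tx + 1L))
  by <- round(seq(0, ny, length.out = best$ty + 1L))
  out <- vector("list", best$tx * best$ty)
  k <- 0L
  for (j in seq_len(best$ty)) for (i in seq_len(best$tx)) {
    k <- k + 1L
    ix <- (bx[i] + 1L):bx[i + 1L]
    iy <- (by[j] + 1L):by[j + 1L]
    out[[k]] <- data.frame(
      tile = k,
      x_um = (mean(range(ix)) - 0.5) * pixel_size_um,
      y_um = (mean(range(iy)) - 0.5) * pixel_size_um,
      mean_intensity = mean(image[ix, iy]),
      tile_w_px = length(ix), tile_h_px = length(iy))
  }
  do.call(rbind, out)
}

#' Per-object proliferation ratio (CFSE / DAPI)
#'
#' Ratio of background-subtracted mean CFSE to mean DAPI intensity inside
#' each segmented object: the dye-dilution proliferation read-out,
#' invariant under common intensity scaling. Objects with zero DAPI signal
#' are dropped with a message.
#'
#' @param cfse_image,dapi_image registered numeric matrices, same size.
#' @param objects result of [detect_objects()] (its `labels` attribute
#'   assigns pixels to objects).
#' @return `objects` with an added `prolif_ratio` column (dropped rows are
#'   removed).
#' @export
proliferation_ratio <- function(cfse_image, dapi_image, objects) {
  stopifnot(all(dim(cfse_image) == dim(dapi_image)))
  lab <- attr(objects, "labels")
  if (is.null(lab) || nrow(objects) == 0L) {
    objects$prolif_ratio <- numeric(0)
    return(objects)
  }
  idx <- lab > 0
  cf <- tapply(cfse_image[idx], lab[idx], mean)
  dp <- tapply(dapi_image[idx], lab[idx], mean)
  ratio <- rep(NA_real_, nrow(objects))
  ratio[as.integer(names(cf))] <- cf / ifelse(dp > 0, dp, NA_real_)
  drop <- which(!is.finite(ratio))
  if (length(drop))
    message(sprintf("proliferation_ratio: dropped %d object(s) with zero DAPI signal",
                    length(drop)))
  out <- objects
  out$prolif_ratio <- ratio
  out <- out[is.finite(out$prolif_ratio), , drop = FALSE]
  attr(out, "labels") <- lab
  out
}
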