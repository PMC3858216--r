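## Non-tracking quantifications: single-cell intensity-ratio time courses,
## lectin-stain area ratios, foci-per-cell counts and kymographs.

.cell_mask <- function(geometry, dim_hw) {
  H <- dim_hw[1]; W <- dim_hw[2]
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  pts <- cbind(as.vector(xs), as.vector(ys))
  matrix(mgcv::in.out(geometry$contour, pts), H, W)
}

#' Single-cell fluorescence-intensity ratio time course
#'
#' Per cell and frame: mean background-corrected intensity inside the cell
#' contour, then the ratio to that cell's maximum over the course (so ratios
#' lie in [0, 1] with 1 at the maximum).  The summary reports mean +/- SD
#' over cells per time point, with the number of cells contributing.
#'
#' @param stack H x W x n_frames array.
#' @param geometries list of `cell_geometry`.
#' @param background either a scalar background level, a logical H x W mask
#'   of a background region (e.g. non-expressing cells), or NULL to use the
#'   median outside all cell contours.
#' @param dt frame interval, min.
#' @return list(per_cell = data.frame(cell_id, frame, time_min, intensity,
#'   ratio), summary = data.frame(frame, time_min, mean_ratio, sd_ratio, n)).
#' @export
intensity_ratio_timecourse <- function(stack, geometries, background = NULL,
                                       dt = 0.5) {
  stopifnot(length(geometries) >= 1)
  nf <- dim(stack)[3]
  masks <- lapply(geometries, .cell_mask, dim_hw = dim(stack)[1:2])
  bgmask <- NULL
  if (is.null(background)) {
    bgmask <- !Reduce(`|`, masks)
  } else if (is.matrix(background)) {
    bgmask <- background
  }
  per <- do.call(rbind, lapply(seq_along(geometries), function(k) {
    vals <- vapply(seq_len(nf), function(f) {
      fr <- stack[, , f]
      bg <- if (is.null(bgmask)) background else stats::median(fr[bgmask])
      mean(fr[masks[[k]]]) - bg
    }, numeric(1))
    mx <- max(vals)
    data.frame(cell_id = geometries[[k]]$cell_id, frame = 0:(nf - 1),
               time_min = (0:(nf - 1)) * dt, intensity = vals,
               ratio = if (mx > 0) pmax(vals, 0) / mx else rep(0, nf))
  }))
  summ <- do.call(rbind, lapply(0:(nf - 1), function(f) {
    r <- per$ratio[per$frame == f & is.finite(per$ratio)]
    data.frame(frame = f, time_min = f * dt, mean_ratio = mean(r),
               sd_ratio = stats::sd(r), n = length(r))
  }))
  list(per_cell = per, summary = summ)
}

#' Stain-area ratio of one cell
#'
#' The specific stain signal is defined by subtracting the background and
#' auto-thresholding (Otsu) the remainder in a neighbourhood of the cell;
#' the ratio is stain area over cell area.  A ratio may exceed 1 only when
#' specific signal extends beyond the cell mask (loosely attached coat),
#' which sets the `loose` flag.
#'
#' @param stain_image 2D matrix (stain channel, registered to the cell
#'   image).
#' @param geometry the cell's `cell_geometry`.
#' @param background scalar background level, or NULL for the image median.
#' @param halo_px neighbourhood margin around the cell considered for stain
#'   signal.
#' @param loose_fraction fraction of stain area outside the mask above which
#'   the loose flag is set.
#' @return data.frame(cell_id, stain_area_px2, cell_area_px2, ratio, loose).
#' @export
stain_area_ratio <- function(stain_image, geometry, background = NULL,
                             halo_px = 8, loose_fraction = 0.05) {
  if (is.null(geometry)) stop("no cell mask: segment the cell image first")
  H <- nrow(stain_image); W <- ncol(stain_image)
  mask <- .cell_mask(geometry, c(H, W))
  if (is.null(background)) background <- stats::median(stain_image)
  spec <- pmax(stain_image - background, 0)
  ## restrict to a neighbourhood of the cell so other cells don't interfere
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  rad <- max(sqrt(rowSums(sweep(geometry$contour, 2, geometry$center)^2)))
  near <- (xs - geometry$center[1])^2 + (ys - geometry$center[2])^2 <=
    (rad + halo_px)^2
  th <- .otsu_threshold(spec[near])
  stain <- near & !is.na(th) & spec > th
  stain_area <- sum(stain)
  ## a 1 px margin absorbs edge pixelation when deciding the loose flag
  grown <- matrix(as.logical(EBImage::imageData(EBImage::dilate(
    EBImage::Image(mask * 1), EBImage::makeBrush(3, "box")))), H, W)
  outside <- sum(stain & !grown)
  data.frame(cell_id = geometry$cell_id, stain_area_px2 = stain_area,
             cell_area_px2 = sum(mask),
             ratio = stain_area / sum(mask),
             loose = stain_area > 0 && outside / stain_area > loose_fraction)
}

#' Count detected foci per cell
#'
#' @param detections detections from one frame (or a max-projection).
#' @param geometries list of `cell_geometry` (cells with no detections count
#'   as zero).
#' @return list(per_cell = data.frame(cell_id, n_foci), summary =
#'   data.frame(mean, sd, max, fraction_with_foci, n_cells)).
#' @export
count_foci_per_cell <- function(detections, geometries) {
  ids <- vapply(geometries, function(g) g$cell_id, 1L)
  counts <- vapply(ids, function(id) sum(detections$cell_id == id), 1L)
  list(per_cell = data.frame(cell_id = ids, n_foci = counts),
       summary = data.frame(mean = mean(counts), sd = stats::sd(counts),
                            max = if (length(counts)) max(counts) else 0L,
                            fraction_with_foci = mean(counts >= 1),
                            n_cells = length(counts)))
}

## bilinear interpolation at 0-based (x, y); clamped to the image
.bilinear <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  x <- pmin(pmax(x, 0), W - 1); y <- pmin(pmax(y, 0), H - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  fx <- x - x0; fy <- y - y0
  img[cbind(y0 + 1, x0 + 1)] * (1 - fx) * (1 - fy) +
    img[cbind(y0 + 1, x1 + 1)] * fx * (1 - fy) +
    img[cbind(y1 + 1, x0 + 1)] * (1 - fx) * fy +
    img[cbind(y1 + 1, x1 + 1)] * fx * fy
}

#' Kymograph by reslicing a stack along a path
#'
#' The path polyline is resampled at 1 px arc-length spacing; per frame,
#' intensities are bilinearly sampled along the path and averaged over
#' `width_px` perpendicular offsets.
#'
#' @param stack H x W x n_frames array.
#' @param path n x 2 matrix of (x, y) polyline vertices, 0-based px.
#' @param width_px averaging width perpendicular to the path (default 3).
#' @return list of class `kymograph`: `image` (rows = time, cols = position),
#'   `path` (resampled), `width_px`.  Errors if the path (or its width
#'   band) exits the image.
#' @export
make_kymograph <- function(stack, path, width_px = 3) {
  stopifnot(length(dim(stack)) == 3, ncol(path) == 2, nrow(path) >= 2)
  H <- dim(stack)[1]; W <- dim(stack)[2]; nf <- dim(stack)[3]
  seg <- sqrt(rowSums(diff(path)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  ss <- seq(0, total, by = 1)
  px <- stats::approx(s, path[, 1], xout = ss)$y
  py <- stats::approx(s, path[, 2], xout = ss)$y
  ## unit normals from the tangent
  tx <- c(diff(px), px[length(px)] - px[length(px) - 1])
  ty <- c(diff(py), py[length(py)] - py[length(py) - 1])
  nrm <- sqrt(tx^2 + ty^2); nrm[nrm == 0] <- 1
  nx <- -ty / nrm; ny <- tx / nrm
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out = width_px)
  allx <- outer(px, offs, function(a, o) a + rep(nx, length.out = length(a)) * o)
  ally <- outer(py, offs, function(a, o) a + rep(ny, length.out = length(a)) * o)
  if (any(allx < 0 | allx > W - 1 | ally < 0 | ally > H - 1))
    stop("kymograph path (including its width band) exits the image")
  kymo <- matrix(0, nf, length(ss))
  for (f in seq_len(nf)) {
    fr <- stack[, , f]
    acc <- 0
    for (k in seq_along(offs)) acc <- acc + .bilinear(fr, allx[, k], ally[, k])
    kymo[f, ] <- acc / length(offs)
  }
  structure(list(image = kymo, path = cbind(px, py), width_px = width_px),
            class = "kymograph")
}

#' Default kymograph path: the brightest ridge of the time-summed stack
#'
#' For orbital cluster motion the ridge around the cell center is traced by
#' taking, in each angular bin about the center, the radius of maximal
#' summed intensity.
#'
#' @param stack H x W x n_frames array.
#' @param geometry the cell's `cell_geometry`.
#' @param n_bins angular bins.
#' @param r_max_px largest radius probed (default: contour max + 2).
#' @return n x 2 path matrix (closed by repeating the first vertex).
#' @export
kymo_default_path <- function(stack, geometry, n_bins = 72, r_max_px = NULL) {
  summed <- apply(stack, c(1, 2), sum)
  if (is.null(r_max_px))
    r_max_px <- max(sqrt(rowSums(sweep(geometry$contour, 2,
                                       geometry$center)^2))) + 2
  angs <- seq(0, 2 * pi, length.out = n_bins + 1)[-(n_bins + 1)]
  rr <- seq(0.5, r_max_px, by = 0.5)
  path <- t(vapply(angs, function(a) {
    x <- geometry$center[1] + rr * cos(a)
    y <- geometry$center[2] - rr * sin(a)
    ok <- x >= 0 & x <= ncol(summed) - 1 & y >= 0 & y <= nrow(summed) - 1
    v <- .bilinear(summed, x[ok], y[ok])
    i <- which.max(v)
    c(x[ok][i], y[ok][i])
  }, numeric(2)))
  rbind(path, path[1, ])
}

#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(t(x$image[nrow(x$image):1, , drop = FALSE]),
                  col = grDevices::gray.colors(256, 0, 1),
                  xlab = "position along path", ylab = "time",
                  axes = FALSE, ...)
  graphics::box()
}
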