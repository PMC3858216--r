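## Cell segmentation and subpixel contour geometry.
##
## Cells are located by a global Otsu threshold; the subpixel outline of each
## connected component is then extracted by marching squares at the
## half-height level between the cell's interior plateau and its local
## background, which pins the contour to the midpoint of the PSF-blurred
## edge independently of where the global threshold happens to fall.  The
## contour is lightly smoothed and represented as a periodic cubic spline;
## area, centroid, eccentricity and the principal axis are computed from
## exact polygon moments of that contour.  The sphere radius p of a rounded
## cell is the mean center-to-contour distance; its SD serves as a
## circularity diagnostic.
##
## Conventions: 0-based pixel-center coordinates, x rightward (columns),
## y downward (rows); angles counterclockwise positive as the image is
## displayed, i.e. measured in the (x, -y) frame.

.otsu_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0) return(NA_real_)
  z <- (img - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(z), range = c(0, 1), levels = 256)
  th * diff(rng) + rng[1]
}

## marching-squares boundary of one labelled component at subpixel precision.
## img: full image, lab: label matrix, id: component label, level: contour
## level (must lie between the component's interior and the background).
.component_contour <- function(img, lab, id, level) {
  sel <- lab == id
  masked <- img
  masked[lab != 0 & !sel] <- min(img)       # suppress other components
  cl <- grDevices::contourLines(x = 0:(nrow(img) - 1), y = 0:(ncol(img) - 1),
                                z = masked, levels = level)
  if (!length(cl)) return(NULL)
  idx <- which(sel, arr.ind = TRUE)
  cen <- c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)   # (x, y) of mask centroid
  for (cc in cl) {
    xy <- cbind(cc$y, cc$x)                  # contourLines x = rows = our y
    closed <- sqrt(sum((xy[1, ] - xy[nrow(xy), ])^2)) < 1e-8
    if (!closed) next
    poly <- xy[-nrow(xy), , drop = FALSE]
    if (nrow(poly) >= 8 &&
        mgcv::in.out(rbind(poly, poly[1, ]), matrix(cen, 1))) {
      return(poly)
    }
  }
  NULL
}

## circular (wrapped) Gaussian smoothing of boundary points
.smooth_closed <- function(poly, sd_pts = 1.5) {
  n <- nrow(poly)
  if (sd_pts <= 0 || n < 8) return(poly)
  h <- min(ceiling(3 * sd_pts), floor((n - 1) / 2))
  w <- stats::dnorm(-h:h, sd = sd_pts)
  w <- w / sum(w)
  sm <- function(v) {
    out <- numeric(n)
    for (k in -h:h) out <- out + w[k + h + 1] * v[((seq_len(n) - 1 + k) %% n) + 1]
    out
  }
  cbind(sm(poly[, 1]), sm(poly[, 2]))
}

## periodic cubic-spline parameterization of a closed boundary
.contour_spline <- function(poly) {
  closed <- rbind(poly, poly[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  t <- c(0, cumsum(seg)) / sum(seg)          # arc-length parameter in [0, 1]
  list(sx = stats::splinefun(t, closed[, 1], method = "periodic"),
       sy = stats::splinefun(t, closed[, 2], method = "periodic"),
       knots = t)
}

## exact region moments of a simple closed polygon (Green's theorem), in the
## y-up frame used for angles.  Returns area, centroid (image coords) and
## normalized central second moments / principal-axis quantities.
.polygon_moments <- function(poly) {
  x <- poly[, 1]
  y <- -poly[, 2]                            # y-up for angle conventions
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  Iyy <- sum(cr * (x^2 + x * xn + xn^2)) / 12        # integral of x^2 dA
  Ixx <- sum(cr * (y^2 + y * yn + yn^2)) / 12        # integral of y^2 dA
  Ixy <- sum(cr * (x * yn + 2 * x * y + 2 * xn * yn + xn * y)) / 24
  s <- sign(A)
  u20 <- s * Iyy / abs(A) - cx^2
  u02 <- s * Ixx / abs(A) - cy^2
  u11 <- s * Ixy / abs(A) - cx * cy
  ang <- 0.5 * atan2(2 * u11, u20 - u02)
  com <- (u20 + u02) / 2
  dif <- sqrt(((u20 - u02) / 2)^2 + u11^2)
  l1 <- com + dif; l2 <- max(com - dif, 0)
  list(area = abs(A), centroid = c(cx, -cy), angle = ang,
       eccentricity = if (l1 > 0) sqrt(1 - l2 / l1) else 0,
       l1 = l1, l2 = l2)
}

## interior plateau and local background levels around one component
.component_levels <- function(img, lab, id, margin = 8) {
  idx <- which(lab == id, arr.ind = TRUE)
  r_eq <- sqrt(nrow(idx) / pi)
  cen <- colMeans(idx)
  d <- sqrt((idx[, 1] - cen[1])^2 + (idx[, 2] - cen[2])^2)
  core <- idx[d <= pmax(r_eq - 2, 1), , drop = FALSE]
  if (!nrow(core)) core <- idx
  plateau <- stats::median(img[core])
  rbox <- range(idx[, 1]); cbox <- range(idx[, 2])
  rows <- max(1, rbox[1] - margin):min(nrow(img), rbox[2] + margin)
  cols <- max(1, cbox[1] - margin):min(ncol(img), cbox[2] + margin)
  sub <- img[rows, cols]
  sublab <- lab[rows, cols]
  bgpix <- sub[sublab == 0]
  bg <- if (length(bgpix)) stats::median(bgpix) else min(img)
  list(plateau = plateau, background = bg)
}

#' Segment cells and build subpixel geometries
#'
#' @param image 2D matrix of counts (rows = y, cols = x).
#' @param pixel_size µm per pixel (used to express the fitted radius in µm).
#' @param min_area_px minimum component area, px^2.
#' @param contour_smooth_sd smoothing of the marching-squares boundary, in
#'   boundary-sample units (default 1.5, leaving residuals around half a
#'   pixel on noisy rims).
#' @param max_eccentricity sphere-fit precondition passed to [fit_sphere];
#'   cells above the bound keep `p_um = NA` (not yet rounded).  Note the
#'   moments eccentricity is roughly sqrt(8 epsilon) for a relative radius
#'   modulation epsilon, so even boundary noise of a tenth of a pixel on a
#'   round cell yields values near 0.3; the default bound 0.6 corresponds to
#'   a minor/major axis ratio of 0.8.
#' @param presmooth_sigma Gaussian presmoothing (px) applied before
#'   thresholding and contour extraction; suppresses shot-noise raggedness of
#'   the contour without moving the half-height edge position
#'   (curvature-induced inward bias is about sigma^2/(2 r), below 0.1 px for
#'   the cells considered here).  0 disables.
#' @param spot_suppress_radius radius (px) of the grayscale-opening
#'   structuring element applied before thresholding; removes bright
#'   diffraction-limited foci (and their projection-dwell ridges) so the
#'   cell-body outline is segmented rather than the spots.  0 disables.
#'   Structures narrower than 2r+1 px vanish; cells must be wider.
#' @return A list of `cell_geometry` objects (empty on a flat or empty
#'   image).  Each has: cell_id, center (x, y px), p_um, p_sd_um, axis_rad,
#'   degenerate_axis, eccentricity, area_px2, contour (closed n x 2 matrix of
#'   subpixel boundary points), spline (periodic cubic parameterization).
#' @export
segment_cells <- function(image, pixel_size = 0.1, min_area_px = 30,
                          contour_smooth_sd = 1.5, max_eccentricity = 0.6,
                          spot_suppress_radius = 4, presmooth_sigma = 1) {
  stopifnot(length(dim(image)) == 2)
  if (spot_suppress_radius > 0) {
    rng <- range(image)
    if (diff(rng) > 0) {
      z <- EBImage::Image((image - rng[1]) / diff(rng))
      brush <- EBImage::makeBrush(2 * spot_suppress_radius + 1, "disc")
      image <- matrix(EBImage::imageData(EBImage::opening(z, brush)),
                      nrow(image), ncol(image)) * diff(rng) + rng[1]
    }
  }
  if (presmooth_sigma > 0) image <- .gauss_blur(image, presmooth_sigma)
  th <- .otsu_threshold(image)
  if (is.na(th)) return(list())
  mask <- image > th
  if (!any(mask) || all(mask)) return(list())
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(lab), nrow(image), ncol(image))
  ids <- setdiff(unique(as.vector(lab)), 0L)
  out <- list()
  for (id in ids) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < min_area_px) next
    lv <- .component_levels(image, lab, id)
    level <- (lv$plateau + lv$background) / 2
    if (!(level > lv$background && level < lv$plateau)) level <- th
    poly <- .component_contour(image, lab, id, level)
    if (is.null(poly)) poly <- .component_contour(image, lab, id, th)
    if (is.null(poly)) next
    poly <- .smooth_closed(poly, contour_smooth_sd)
    mom <- .polygon_moments(poly)
    g <- structure(list(
      cell_id = length(out) + 1L,
      center = mom$centroid,
      area_px2 = mom$area,
      contour = rbind(poly, poly[1, ]),
      spline = .contour_spline(poly),
      eccentricity = mom$eccentricity,
      axis_rad = NA_real_, degenerate_axis = NA,
      axis_endpoints = NULL,
      p_um = NA_real_, p_sd_um = NA_real_,
      pixel_size = pixel_size), class = "cell_geometry")
    ax <- estimate_major_axis(g)
    g$axis_rad <- ax$angle
    g$degenerate_axis <- ax$degenerate
    g$axis_endpoints <- ax$endpoints
    fit <- tryCatch(fit_sphere(g, pixel_size,
                               max_eccentricity = max_eccentricity),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      g$p_um <- fit$p_um
      g$p_sd_um <- fit$p_sd_um
    }
    out[[length(out) + 1L]] <- g
  }
  out
}

#' Major-axis direction and endpoints of a segmented cell
#'
#' The axis is the principal axis of the cell region's second moments
#' (computed exactly from the subpixel contour polygon).  The endpoints are
#' contour points near each axis ray chosen by a weighted score that rewards
#' high spline curvature and penalizes angular deviation from the
#' centerline.  Cells with eccentricity below `degenerate_below` (default
#' 0.45, i.e. minor/major axis ratio above about 0.9 -- the moments
#' eccentricity is sqrt-amplified for nearly round shapes) are spheres for
#' which no axis is defined: the angle defaults to 0 (image x axis) and
#' the degenerate flag is set, so downstream theta values are arbitrary up to
#' a rotation (all distances are rotation-invariant).
#'
#' @param geometry a `cell_geometry`.
#' @param w_curvature,w_angle score weights (curvature is normalized to its
#'   contour maximum; angular deviation is in radians).
#' @param degenerate_below eccentricity below which the axis is degenerate.
#' @param n_samples dense spline samples used for scoring.
#' @return list(angle, degenerate, endpoints (2 x 2 matrix)).
#' @export
estimate_major_axis <- function(geometry, w_curvature = 1, w_angle = 1,
                                degenerate_below = 0.45, n_samples = 400) {
  poly <- geometry$contour
  if (is.null(poly) || nrow(poly) < 8)
    stop("degenerate contour (<8 points): segmentation failed")
  mom <- .polygon_moments(poly[-nrow(poly), , drop = FALSE])
  ang <- mom$angle
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  ecc <- geometry$eccentricity
  if (!is.finite(ecc)) ecc <- mom$eccentricity
  degenerate <- ecc < degenerate_below
  if (degenerate) ang <- 0

  ## dense samples, curvature and polar angle about the center
  sp <- geometry$spline
  tt <- seq(0, 1, length.out = n_samples + 1)[-(n_samples + 1)]
  px <- sp$sx(tt); py <- sp$sy(tt)
  dx <- sp$sx(tt, deriv = 1); dy <- sp$sy(tt, deriv = 1)
  ddx <- sp$sx(tt, deriv = 2); ddy <- sp$sy(tt, deriv = 2)
  kappa <- abs(dx * ddy - dy * ddx) / pmax((dx^2 + dy^2)^1.5, 1e-12)
  kn <- if (max(kappa) > 0) kappa / max(kappa) else kappa
  pang <- atan2(-(py - geometry$center[2]), px - geometry$center[1])
  pick <- function(ray) {
    dev <- abs(atan2(sin(pang - ray), cos(pang - ray)))
    cand <- which(dev < pi / 4)
    if (!length(cand)) cand <- which.min(dev)
    sc <- w_curvature * kn[cand] - w_angle * dev[cand]
    cand[which.max(sc)]
  }
  i1 <- pick(ang); i2 <- pick(ang + pi)
  list(angle = ang, degenerate = degenerate,
       endpoints = rbind(c(px[i1], py[i1]), c(px[i2], py[i2])))
}

#' Fit the spore sphere radius from a rounded cell's contour
#'
#' p is the mean distance from the cell center to the spline-sampled contour,
#' converted to µm; the SD of those distances is reported as a circularity
#' diagnostic.  Cells whose eccentricity exceeds the bound have not rounded
#' into spores yet and are rejected.
#'
#' @param geometry a `cell_geometry`.
#' @param pixel_size µm per px.
#' @param max_eccentricity precondition bound (default 0.6; see
#'   [segment_cells] for why apparently strict roundness corresponds to
#'   values well above zero in the moments eccentricity).
#' @param n_samples contour samples.
#' @return list(p_um, p_sd_um).
#' @export
fit_sphere <- function(geometry, pixel_size = geometry$pixel_size,
                       max_eccentricity = 0.6, n_samples = 400) {
  stopifnot(pixel_size > 0)
  if (is.finite(geometry$eccentricity) &&
      geometry$eccentricity > max_eccentricity)
    stop("eccentricity ", signif(geometry$eccentricity, 3),
         " exceeds bound ", max_eccentricity,
         ": cell has not rounded into a spore")
  sp <- geometry$spline
  tt <- seq(0, 1, length.out = n_samples + 1)[-(n_samples + 1)]
  d <- sqrt((sp$sx(tt) - geometry$center[1])^2 +
            (sp$sy(tt) - geometry$center[2])^2)
  list(p_um = mean(d) * pixel_size, p_sd_um = stats::sd(d) * pixel_size)
}
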