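## Spherical coordinate system for foci on the surface of a spore.
##
## A detection in the image plane is first expressed in polar coordinates
## (r, theta) about the cell center, with theta measured counterclockwise
## from the major cell axis (y-up convention: the image y axis points down,
## so "counterclockwise" refers to the image as displayed).  Because foci sit
## on the surface of a sphere of radius p, the planar radius r is the
## projection of the surface position and the elevation angle phi off the
## imaging plane follows from phi = arccos(r / p).  The 3D unit vector of a
## focus is n = (cos(phi) cos(theta), cos(phi) sin(theta), sin(phi)).

#' Convert a planar detection to polar coordinates about the cell center
#'
#' @param x_px,y_px subpixel position of the focus (0-based pixel centers,
#'   x rightward, y downward).
#' @param geometry a [cell_geometry] object (provides center and major axis).
#' @param pixel_size pixel size in micrometres per pixel.
#' @return A list with `r` (µm, distance from the cell center) and `theta`
#'   (radians in (-pi, pi], counterclockwise from the major axis; 0 by
#'   convention for a focus exactly at the center).
#' @export
to_polar <- function(x_px, y_px, geometry, pixel_size) {
  stopifnot(pixel_size > 0)
  dx <- (x_px - geometry$center[1]) * pixel_size
  ## image y points down; flip so positive theta is counterclockwise on screen
  dy <- -(y_px - geometry$center[2]) * pixel_size
  r <- sqrt(dx^2 + dy^2)
  theta <- ifelse(r == 0, 0, atan2(dy, dx) - geometry$axis_rad)
  ## wrap to (-pi, pi]
  theta <- theta - 2 * pi * ceiling((theta - pi) / (2 * pi))
  list(r = r, theta = theta)
}

#' Lift polar coordinates onto the spore sphere
#'
#' The elevation angle is `phi = arccos(r / p)`: a focus on the equatorial
#' boundary (r = p) has phi = 0, a focus projecting onto the cell center has
#' phi = pi/2.  Localization noise can put a detection marginally outside the
#' fitted circle; r is then clamped to p and the clamp recorded.
#'
#' @param r planar distance from the cell center, µm.
#' @param theta angular coordinate, radians.
#' @param p sphere radius, µm.
#' @return A list with `p`, `theta`, `phi` and logical `clamped`.
#' @export
to_spherical <- function(r, theta, p) {
  stopifnot(p > 0)
  clamped <- r > p
  phi <- acos(pmin(r / p, 1))
  list(p = p, theta = theta, phi = phi, clamped = clamped)
}

#' 3D unit vector of a spherical coordinate
#'
#' @param theta,phi angular coordinates in radians.
#' @return An n x 3 matrix of unit vectors
#'   (cos(phi) cos(theta), cos(phi) sin(theta), sin(phi)).
#' @export
spherical_to_unit <- function(theta, phi) {
  cbind(cos(phi) * cos(theta), cos(phi) * sin(theta), sin(phi))
}

#' Great-circle (orthodromic) distance between two surface positions
#'
#' Evaluates
#' d = p * arccos(cos(t1) cos(f1) cos(t2) cos(f2) +
#'                sin(t1) cos(f1) sin(t2) cos(f2) + sin(f1) sin(f2)),
#' the arc length between two points on a sphere of radius p.  The argument
#' of arccos is clipped to [-1, 1] against rounding.  Vectorized.
#'
#' @param theta1,phi1,theta2,phi2 angular coordinates, radians.
#' @param p sphere radius (µm); either a scalar or per-element.  Comparing
#'   positions on spheres of different radii is an error (cross-cell
#'   comparison), controlled by `p_tol`.
#' @param p2 optional second radius, checked against `p`.
#' @param p_tol relative tolerance on radius agreement (default 1e-6).
#' @return arc length(s), same unit as p.
#' @export
orthodromic_distance <- function(theta1, phi1, theta2, phi2, p, p2 = p,
                                 p_tol = 1e-6) {
  if (any(abs(p2 - p) > p_tol * pmax(abs(p), abs(p2)))) {
    stop("sphere radii differ beyond tolerance: positions belong to different cells")
  }
  arg <- cos(theta1) * cos(phi1) * cos(theta2) * cos(phi2) +
    sin(theta1) * cos(phi1) * sin(theta2) * cos(phi2) +
    sin(phi1) * sin(phi2)
  p * acos(pmin(pmax(arg, -1), 1))
}

#' Orthodromic distance from planar (Euclidean) positions
#'
#' Lifts each planar point to the upper hemisphere (z = sqrt(p^2 - r^2)),
#' computes the 3D chord c between the lifted points and returns the arc
#' 2 p arcsin(c / (2p)).  Algebraically identical to [orthodromic_distance]
#' applied to the corresponding spherical coordinates.
#'
#' @param xy1,xy2 planar positions (px), length-2 vectors or n x 2 matrices.
#' @param center cell center (px), length-2.
#' @param p sphere radius, µm.
#' @param pixel_size µm per px.
#' @return arc length(s) in µm.
#' @export
euclidean_to_orthodromic <- function(xy1, xy2, center, p, pixel_size) {
  lift <- function(xy) {
    xy <- rbind(xy)
    dx <- (xy[, 1] - center[1]) * pixel_size
    dy <- -(xy[, 2] - center[2]) * pixel_size
    r2 <- pmin(dx^2 + dy^2, p^2)          # clamp points outside the disk
    s <- ifelse(dx^2 + dy^2 > 0, sqrt(r2 / pmax(dx^2 + dy^2, 1e-300)), 1)
    cbind(dx * s, dy * s, sqrt(pmax(p^2 - r2, 0)))
  }
  a <- lift(xy1)
  b <- lift(xy2)
  chord <- sqrt(rowSums((a - b)^2))
  as.numeric(2 * p * asin(pmin(chord / (2 * p), 1)))
}
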