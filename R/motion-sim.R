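## Ground-truth surface motion on a sphere.
##
## Four regimes emulate the behaviours seen for envelope-complex clusters on
## sporulating cells: "directed" (processive transport along a great circle),
## "diffusive" (free surface diffusion), "arrested" (motor-dead jitter about
## a fixed anchor) and "directed_with_reversals" (processive runs whose sense
## flips as a Poisson process, the phenotype of cells lacking the guiding
## surface polymer).

#' Motion parameters for a simulated surface trajectory
#'
#' @param regime one of "directed", "diffusive", "arrested",
#'   "directed_with_reversals".
#' @param v_true drift speed along the great circle, µm/min (ignored for
#'   diffusive/arrested).
#' @param D_true surface diffusion coefficient, µm^2/min.  For the arrested
#'   regime this sets the residual jitter about the anchor point
#'   (per-axis variance 2 D dt per frame, uncorrelated between frames).
#' @param reversal_rate Poisson rate of direction reversals, events/min
#'   (directed_with_reversals only).
#' @param p_true sphere radius, µm.
#' @param dt frame interval, min.
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed; NULL leaves the RNG state alone.
#' @return A validated list of class `motion_params`.
#' @export
motion_params <- function(regime = c("directed", "diffusive", "arrested",
                                     "directed_with_reversals"),
                          v_true = 0.12, D_true = 0.012, reversal_rate = 0,
                          p_true = 0.75, dt = 0.5, n_frames = 60, seed = NULL) {
  regime <- match.arg(regime)
  if (regime %in% c("diffusive", "arrested")) v_true <- 0
  stopifnot(v_true >= 0, D_true >= 0, p_true > 0, dt > 0, n_frames >= 2,
            reversal_rate >= 0)
  structure(list(regime = regime, v_true = v_true, D_true = D_true,
                 reversal_rate = reversal_rate, p_true = p_true, dt = dt,
                 n_frames = as.integer(n_frames), seed = seed),
            class = "motion_params")
}

## random unit vector and a random unit tangent at it
.random_frame <- function() {
  x <- stats::rnorm(3)
  x <- x / sqrt(sum(x^2))
  d <- stats::rnorm(3)
  d <- d - sum(d * x) * x
  d <- d / sqrt(sum(d^2))
  list(x = x, d = d)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Simulate one ground-truth trajectory on the sphere
#'
#' Directed motion advances along a randomly oriented great circle at angular
#' rate v/p per unit time, with tangential Brownian jitter of coefficient D
#' superimposed.  Diffusive motion takes tangent-plane Gaussian steps with
#' per-axis variance 2 D dt, reprojected onto the sphere (valid for steps much
#' smaller than p).  Arrested foci jitter about a fixed anchor.  Reversing
#' foci flip their sense of rotation as a Poisson process.
#'
#' @param params a [motion_params] object.
#' @param focus_id identifier stored in the output.
#' @return A data.frame of class `surface_trajectory` with one row per frame:
#'   focus_id, frame (0-based), time_min, x_um, y_um, z_um (position relative
#'   to the sphere center; z along the optical axis), p_um, theta_rad,
#'   phi_rad (phi = arccos(r/p) of the planar projection, in [0, pi/2]),
#'   and step_um (true arc length from the previous frame, NA at frame 0).
#' @export
simulate_surface_trajectory <- function(params, focus_id = 1L) {
  stopifnot(inherits(params, "motion_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_frames
  p <- params$p_true
  dt <- params$dt
  sd_step <- sqrt(2 * params$D_true * dt)     # µm, per tangent axis
  fr <- .random_frame()
  x <- fr$x
  d <- fr$d
  X <- matrix(NA_real_, n, 3)
  X[1, ] <- x

  if (params$regime == "arrested") {
    anchor <- x
    ad <- d
    for (i in seq_len(n)) {
      b <- .cross3(anchor, ad)
      st <- stats::rnorm(2, 0, sd_step) / p
      xi <- anchor + st[1] * ad + st[2] * b
      X[i, ] <- xi / sqrt(sum(xi^2))
    }
  } else {
    ang <- params$v_true * dt / p             # angular advance per frame
    pflip <- if (params$regime == "directed_with_reversals")
      1 - exp(-params$reversal_rate * dt) else 0
    for (i in 2:n) {
      if (pflip > 0 && stats::runif(1) < pflip) d <- -d
      if (params$regime %in% c("directed", "directed_with_reversals") && ang > 0) {
        xn <- x * cos(ang) + d * sin(ang)
        dn <- -x * sin(ang) + d * cos(ang)    # parallel transport of heading
      } else {
        xn <- x
        dn <- d
      }
      if (sd_step > 0) {
        b <- .cross3(xn, dn)
        st <- stats::rnorm(2, 0, sd_step) / p
        xn <- xn + st[1] * dn + st[2] * b
        xn <- xn / sqrt(sum(xn^2))
        dn <- dn - sum(dn * xn) * xn
        dn <- dn / sqrt(sum(dn^2))
      }
      x <- xn
      d <- dn
      X[i, ] <- x
    }
  }

  P <- X * p
  r_plane <- sqrt(P[, 1]^2 + P[, 2]^2)
  theta <- ifelse(r_plane == 0, 0, atan2(P[, 2], P[, 1]))
  phi <- acos(pmin(r_plane / p, 1))
  step <- c(NA_real_,
            p * acos(pmin(pmax(rowSums(X[-n, , drop = FALSE] *
                                       X[-1, , drop = FALSE]), -1), 1)))
  out <- data.frame(focus_id = focus_id,
                    frame = 0:(n - 1),
                    time_min = (0:(n - 1)) * dt,
                    x_um = P[, 1], y_um = P[, 2], z_um = P[, 3],
                    p_um = p, theta_rad = theta, phi_rad = phi,
                    step_um = step)
  class(out) <- c("surface_trajectory", "data.frame")
  attr(out, "params") <- params
  out
}
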