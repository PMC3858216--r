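## Trajectory statistics and MSD-based motion decomposition.
##
## All displacements are orthodromic (great-circle) arc lengths on the spore
## sphere.  The ensemble MSD is fitted without intercept to
## MSD(t) = 4 D t + v^2 t^2, separating the apparent surface diffusion
## coefficient D from the mean transport velocity v.  A motion-class label
## (directed / diffusive / subdiffusive / arrested) is derived from the
## log-log MSD slope alpha and the share of the quadratic term.

.track_steps <- function(track, lag = 1) {
  n <- nrow(track)
  if (n <= lag) return(numeric(0))
  i <- seq_len(n - lag)
  orthodromic_distance(track$theta_rad[i], track$phi_rad[i],
                       track$theta_rad[i + lag], track$phi_rad[i + lag],
                       track$p_um[i], track$p_um[i + lag])
}

#' Instantaneous speeds along a track
#'
#' Orthodromic distance between consecutive observations divided by their
#' time difference; one value per consecutive pair.
#'
#' @param track one track's data.frame (time_min, theta_rad, phi_rad, p_um).
#' @return numeric vector, µm/min.
#' @export
instantaneous_speeds <- function(track) {
  stopifnot(nrow(track) >= 2)
  track <- track[order(track$time_min), , drop = FALSE]
  .track_steps(track, 1) / diff(track$time_min)
}

#' Cumulated path length along a track
#' @param track one track's data.frame.
#' @return running sum of consecutive orthodromic steps, µm (0 at the first
#'   observation).
#' @export
cumulated_distance <- function(track) {
  track <- track[order(track$time_min), , drop = FALSE]
  c(0, cumsum(.track_steps(track, 1)))
}

#' Orthodromic distance from the track origin at each observation
#' @param track one track's data.frame.
#' @return numeric vector, µm (0 at the first observation).
#' @export
distance_from_origin <- function(track) {
  track <- track[order(track$time_min), , drop = FALSE]
  orthodromic_distance(track$theta_rad[1], track$phi_rad[1],
                       track$theta_rad, track$phi_rad,
                       track$p_um[1], track$p_um)
}

#' Ensemble mean square displacement over lag time
#'
#' Per track, the MSD is time-averaged over all observation pairs at each
#' frame lag; the ensemble curve is the pair-count-weighted mean across
#' tracks.  Lags are restricted to `max_lag_fraction` of the longest track.
#'
#' @param tracks a `tracks` data.frame or a list of per-track data.frames
#'   (see [split_tracks]); each track needs >= 3 observations to contribute.
#' @param dt frame interval, min.
#' @param max_lag_fraction largest lag as a fraction of the longest track's
#'   span (default 0.5).
#' @param paper_min_tracks ensemble curves built from fewer tracks are
#'   flagged (`compliant = FALSE`); the reference protocol requires at least
#'   15 trajectories.
#' @return data.frame of class `msd_curve`: lag (frames), t_min, msd (µm^2),
#'   n_pairs; attributes n_tracks, compliant.
#' @export
compute_msd <- function(tracks, dt = 0.5, max_lag_fraction = 0.5,
                        paper_min_tracks = 15) {
  if (is.data.frame(tracks)) tracks <- split_tracks(tracks)
  tracks <- tracks[vapply(tracks, nrow, 1L) >= 3]
  stopifnot(length(tracks) >= 1)
  span <- max(vapply(tracks, function(tr) diff(range(tr$frame)), 1))
  max_lag <- max(1L, floor(span * max_lag_fraction))
  agg_sum <- numeric(max_lag)
  agg_n <- integer(max_lag)
  for (tr in tracks) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    fr <- tr$frame
    for (L in seq_len(max_lag)) {
      ## pairs separated by exactly L frames (tracks may have gaps)
      j <- match(fr + L, fr)
      i <- which(!is.na(j))
      if (!length(i)) next
      d <- orthodromic_distance(tr$theta_rad[i], tr$phi_rad[i],
                                tr$theta_rad[j[i]], tr$phi_rad[j[i]],
                                tr$p_um[i], tr$p_um[j[i]])
      agg_sum[L] <- agg_sum[L] + sum(d^2)
      agg_n[L] <- agg_n[L] + length(d)
    }
  }
  keep <- agg_n > 0
  out <- data.frame(lag = seq_len(max_lag)[keep],
                    t_min = seq_len(max_lag)[keep] * dt,
                    msd = agg_sum[keep] / agg_n[keep],
                    n_pairs = agg_n[keep])
  attr(out, "n_tracks") <- length(tracks)
  attr(out, "p_um") <- mean(vapply(tracks, function(tr) tr$p_um[1], 1))
  attr(out, "compliant") <- length(tracks) >= paper_min_tracks
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Second-order MSD fit: MSD(t) = 4 D t + v^2 t^2
#'
#' Nonnegative least squares on the basis {4t, t^2} (no intercept, matching
#' the zero-offset relation), weighted by the number of pairs per lag.  The
#' relation is the planar small-arc expansion of motion on a sphere, so the
#' (v, D) fit is restricted to lags whose RMS angular displacement
#' sqrt(msd)/p stays below `max_rms_angle` (default 0.5 rad, where the
#' expansion is accurate to a few percent; at larger arcs great-circle
#' distances saturate and the hemisphere-projection ambiguity depresses the
#' curve, both of which bias v downward).  The shape statistics -- the
#' log-log slope alpha and the quadratic share of the MSD -- are computed
#' over the first `fit_fraction` of the curve's lags, since they describe
#' the observable curve rather than the small-arc model.  An optional
#' localization-noise offset term can be enabled.
#'
#' @param curve an `msd_curve` (>= 4 lag points).
#' @param fit_fraction fraction of lags used for the shape statistics and as
#'   the outer bound of the (v, D) fit (default 0.5, the first half).
#' @param max_rms_angle small-arc validity bound, radians, applied when the
#'   curve carries its sphere radius (`p_um` attribute); at least 4 lags are
#'   always kept.  Inf disables.
#' @param with_offset add a constant offset term (default FALSE).
#' @return list of class `motion_estimate`: v (µm/min), D (µm^2/min), alpha,
#'   offset, residual (weighted RMS), msd_last (MSD at the last fitted lag),
#'   quadratic_fraction (share of v^2 t^2 at that lag), n_tracks, regime
#'   (filled by [classify_motion]).
#' @export
fit_msd_directed <- function(curve, fit_fraction = 0.5, max_rms_angle = 0.5,
                             with_offset = FALSE) {
  stopifnot(nrow(curve) >= 4)
  nfit <- max(4L, ceiling(nrow(curve) * fit_fraction))
  cv <- curve[seq_len(min(nfit, nrow(curve))), , drop = FALSE]
  p <- attr(curve, "p_um")
  sel <- seq_len(nrow(cv))
  if (!is.null(p) && is.finite(p) && is.finite(max_rms_angle)) {
    ok <- which(cv$msd <= (max_rms_angle * p)^2)
    sel <- seq_len(max(4L, if (length(ok)) max(ok) else 0L))
    sel <- sel[sel <= nrow(cv)]
  }
  t <- cv$t_min[sel]; m <- cv$msd[sel]; w <- cv$n_pairs[sel]
  if (all(m == 0)) {
    est <- list(v = 0, D = 0, alpha = NA_real_, offset = 0, residual = 0,
                msd_last = 0, quadratic_fraction = 0,
                n_tracks = attr(curve, "n_tracks"), regime = "arrested")
    class(est) <- "motion_estimate"
    return(est)
  }
  A <- if (with_offset) cbind(4 * t, t^2, 1) else cbind(4 * t, t^2)
  ## weighted least squares with nonnegativity on D and v^2 by active set:
  ## solve unconstrained; if a coefficient is negative, refit with it pinned
  ## at zero (2-parameter problem, so this is exact NNLS)
  wls <- function(A) solve(t(A * w) %*% A, t(A * w) %*% m)
  co <- drop(wls(A))
  if (co[1] < 0 || co[2] < 0) {
    co1 <- co2 <- NULL
    ss <- function(co, A) sum(w * (m - A %*% co)^2)
    A1 <- A[, -1, drop = FALSE]; c1 <- drop(wls(A1))   # D = 0
    if (all(c1[1] >= 0)) co1 <- c(0, c1)
    A2 <- A[, -2, drop = FALSE]; c2 <- drop(wls(A2))   # v = 0
    if (all(c2[1] >= 0)) co2 <- append(c2, 0, after = 1)
    cand <- Filter(Negate(is.null), list(co1, co2))
    if (!length(cand)) cand <- list(rep(0, ncol(A)))
    co <- cand[[which.min(vapply(cand, ss, numeric(1), A = A))]]
  }
  ## snap numerically-zero coefficients (sqrt would amplify solver noise)
  co[1:2][abs(co[1:2]) < 1e-9 * max(abs(co[1:2]), 1e-300)] <- 0
  D <- co[1]; v <- sqrt(max(co[2], 0))
  offset <- if (with_offset) co[3] else 0
  resid <- sqrt(sum(w * (m - A %*% co)^2) / sum(w))
  ## shape statistics over the full first-fraction range
  ts <- cv$t_min; ms <- cv$msd
  pos <- ms > 0
  alpha <- if (sum(pos) >= 2)
    unname(stats::coef(stats::lm(log(ms[pos]) ~ log(ts[pos])))[2]) else NA_real_
  tl <- ts[length(ts)]
  mq <- co[2] * tl^2
  est <- list(v = v, D = D, alpha = alpha, offset = offset, residual = resid,
              msd_last = ms[length(ms)],
              quadratic_fraction = if (4 * D * tl + mq > 0)
                mq / (4 * D * tl + mq) else 0,
              n_tracks = attr(curve, "n_tracks"), regime = NA_character_)
  class(est) <- "motion_estimate"
  est
}

#' Classify the motion regime from a fitted MSD
#'
#' Declared conventions: "arrested" when the MSD at the last fitted lag is
#' below `noise_floor`; "subdiffusive" when alpha < `alpha_sub`; "directed"
#' when alpha > `alpha_dir` and the quadratic term carries at least half the
#' MSD at the last fitted lag; otherwise "diffusive".
#'
#' @param estimate a `motion_estimate` from [fit_msd_directed].
#' @param noise_floor µm^2 (default 0.01, i.e. 100 nm RMS displacement).
#' @param alpha_sub,alpha_dir log-log-slope thresholds (0.9 and 1.2).
#' @return the estimate with `regime` filled in.
#' @export
classify_motion <- function(estimate, noise_floor = 0.01, alpha_sub = 0.9,
                            alpha_dir = 1.2) {
  stopifnot(inherits(estimate, "motion_estimate"))
  estimate$regime <-
    if (estimate$msd_last < noise_floor) "arrested"
    else if (is.na(estimate$alpha) || estimate$alpha < alpha_sub) "subdiffusive"
    else if (estimate$alpha > alpha_dir && estimate$quadratic_fraction >= 0.5)
      "directed"
    else "diffusive"
  estimate
}

#' @export
print.motion_estimate <- function(x, ...) {
  cat("MSD second-order fit (MSD = 4Dt + v^2 t^2)\n")
  cat(sprintf("  v      = %.4f um/min\n", x$v))
  cat(sprintf("  D      = %.5f um^2/min\n", x$D))
  cat(sprintf("  alpha  = %.3f (log-log MSD slope)\n", x$alpha))
  cat(sprintf("  regime = %s  (n_tracks = %s)\n",
              ifelse(is.na(x$regime), "<unclassified>", x$regime),
              x$n_tracks))
  invisible(x)
}
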