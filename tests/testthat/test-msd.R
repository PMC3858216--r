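## build a track data.frame directly from spherical coordinates
make_track <- function(theta, phi, p = 0.75, dt = 0.5, track_id = 1) {
  data.frame(track_id = track_id, cell_id = 1, frame = seq_along(theta) - 1,
             time_min = (seq_along(theta) - 1) * dt, p_um = p,
             theta_rad = theta, phi_rad = phi, x_px = 0, y_px = 0,
             intensity = 1, clamped = FALSE)
}

## package trajectory -> track table on the true (signed) hemisphere, so
## these tests exercise the motion statistics themselves; the upper-
## hemisphere projection ambiguity is covered by the end-to-end tests
traj_track <- function(tr, id = 1) {
  ph <- asin(tr$z_um / tr$p_um)
  make_track(tr$theta_rad, ph, p = tr$p_um[1],
             dt = diff(tr$time_min[1:2]), track_id = id)
}

test_that("stationary tracks have zero speeds, distances and MSD", {
  tk <- make_track(rep(0.4, 10), rep(0.2, 10))
  expect_equal(instantaneous_speeds(tk), rep(0, 9))
  expect_equal(cumulated_distance(tk), rep(0, 10))
  expect_equal(distance_from_origin(tk), rep(0, 10))
  curve <- compute_msd(list(tk), dt = 0.5)
  expect_true(all(curve$msd == 0))
  est <- classify_motion(fit_msd_directed(curve))
  expect_equal(est$regime, "arrested")
  expect_equal(est$v, 0)
  expect_equal(est$D, 0)
})

test_that("noiseless directed tracks have exact speeds and monotone escape", {
  mp <- motion_params("directed", v_true = 0.12, D_true = 0, seed = 3)
  tr <- simulate_surface_trajectory(mp)
  n <- spherical_to_unit(tr$theta_rad, tr$phi_rad)
  n[, 3] <- sign(tr$z_um) * n[, 3]
  ## reconstruct angles on the true hemisphere so geometry is exact
  th <- atan2(n[, 2], n[, 1]); ph <- asin(n[, 3])
  d <- 0.75 * acos(pmin(1, rowSums(n[-60, ] * n[-1, ])))
  expect_lt(max(abs(d / 0.5 - 0.12)), 1e-9)
  ## distance from origin grows monotonically while the arc stays under pi*p
  tk <- make_track(th, ph)
  dfo <- distance_from_origin(tk)
  ## escape is monotone while the cumulated arc stays below pi * p
  n_mono <- floor(pi * 0.75 / (0.12 * 0.5))
  expect_true(all(diff(dfo[1:n_mono]) > -1e-12))
  expect_true(all(cumulated_distance(tk) >= dfo - 1e-7))
})

test_that("cumulated distance dominates distance from origin in every regime", {
  set.seed(11)
  for (rg in c("directed", "diffusive", "arrested", "directed_with_reversals")) {
    mp <- motion_params(rg, reversal_rate = 2, seed = sample(1e6, 1))
    tk <- traj_track(simulate_surface_trajectory(mp))
    expect_true(all(cumulated_distance(tk) >= distance_from_origin(tk) - 1e-7))
  }
})

test_that("diffusive escape grows like sqrt(t) against a Monte-Carlo oracle", {
  set.seed(21)
  D <- 0.012; dt <- 0.5; p <- 0.75
  nfr <- 40
  dfo2 <- matrix(0, 100, nfr)
  for (k in 1:100) {
    mp <- motion_params("diffusive", D_true = D, dt = dt, n_frames = nfr,
                        p_true = p, seed = sample(1e6, 1))
    tk <- traj_track(simulate_surface_trajectory(mp))
    dfo2[k, ] <- distance_from_origin(tk)^2
  }
  m <- colMeans(dfo2)
  tt <- (seq_len(nfr) - 1) * dt
  ## mean squared escape ~ 4 D t in the small-arc regime (first ten lags)
  fit <- coef(lm(m[2:10] ~ 0 + tt[2:10]))[1]
  expect_equal(unname(fit) / (4 * D), 1, tolerance = 0.15)
})

test_that("analytic MSD curves are fitted exactly", {
  tl <- (1:12) * 0.5
  mk <- function(msd) structure(
    data.frame(lag = 1:12, t_min = tl, msd = msd, n_pairs = 50 - (1:12)),
    class = c("msd_curve", "data.frame"), n_tracks = 20)
  est <- fit_msd_directed(mk(tl^2))
  expect_equal(est$v, 1, tolerance = 1e-9)
  expect_equal(est$D, 0, tolerance = 1e-9)
  est <- fit_msd_directed(mk(4 * tl))
  expect_equal(est$v, 0, tolerance = 1e-9)
  expect_equal(est$D, 1, tolerance = 1e-9)
  ## mixed curve with the reference values
  est <- fit_msd_directed(mk(4 * 0.012 * tl + 0.12^2 * tl^2))
  expect_equal(est$v, 0.12, tolerance = 1e-9)
  expect_equal(est$D, 0.012, tolerance = 1e-9)
})

test_that("noiseless directed MSD matches (v t)^2 at small arcs", {
  mp <- motion_params("directed", v_true = 0.12, D_true = 0, seed = 17)
  curve <- compute_msd(list(traj_track(simulate_surface_trajectory(mp))),
                       dt = 0.5)
  expect_equal(curve$msd[1:3], (0.12 * curve$t_min[1:3])^2, tolerance = 0.02)
})

test_that("ensemble MSD flags non-compliant track counts", {
  mp <- motion_params("directed", seed = 1)
  curve <- compute_msd(list(traj_track(simulate_surface_trajectory(mp))),
                       dt = 0.5)
  expect_false(attr(curve, "compliant"))
  expect_equal(attr(curve, "n_tracks"), 1)
})

test_that("generative regimes are recovered from ensemble MSD fits", {
  fit_preset <- function(preset, seed) {
    set.seed(seed)
    mp <- preset_motion(preset)
    tks <- lapply(1:25, function(i) {
      mp$seed <- NULL
      traj_track(simulate_surface_trajectory(mp), id = i)
    })
    classify_motion(fit_msd_directed(compute_msd(tks, dt = 0.5)))
  }
  for (s in 1:3) {
    expect_equal(fit_preset("WT", s)$regime, "directed")
    expect_equal(fit_preset("exoA", 100 + s)$regime, "diffusive")
    expect_true(fit_preset("aglQ", 200 + s)$regime %in%
                  c("arrested", "subdiffusive"))
  }
})

test_that("WT parameter recovery from generative trajectories is unbiased", {
  set.seed(77)
  mp <- preset_motion("WT")
  mp$seed <- NULL
  tks <- lapply(1:25, function(i) traj_track(simulate_surface_trajectory(mp), i))
  est <- fit_msd_directed(compute_msd(tks, dt = 0.5))
  expect_lt(abs(est$v - 0.12), 0.05)
  expect_lt(abs(est$D - 0.012), 0.007)
})
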