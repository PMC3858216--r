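test_that("trajectories stay on the sphere in every regime", {
  for (rg in c("directed", "diffusive", "arrested", "directed_with_reversals")) {
    mp <- motion_params(rg, reversal_rate = 2, seed = 4)
    tr <- simulate_surface_trajectory(mp)
    expect_lt(max(abs(sqrt(tr$x_um^2 + tr$y_um^2 + tr$z_um^2) - 0.75)), 1e-9)
    expect_equal(nrow(tr), 60)
  }
})

test_that("zero-motion arrested trajectory never moves", {
  mp <- motion_params("arrested", D_true = 0, seed = 1)
  tr <- simulate_surface_trajectory(mp)
  expect_equal(max(tr$step_um[-1]), 0)
  expect_equal(diff(range(tr$x_um)), 0)
})

test_that("noiseless directed kinematics are exact", {
  mp <- motion_params("directed", v_true = 0.12, D_true = 0, p_true = 0.75,
                      dt = 0.5, n_frames = 60, seed = 2)
  tr <- simulate_surface_trajectory(mp)
  expect_lt(max(abs(tr$step_um[-1] - 0.12 * 0.5)), 1e-9)
  expect_equal(sum(tr$step_um[-1]), 3.54, tolerance = 1e-9)
})

test_that("diffusive per-step arc MSD matches an independent tangent-step oracle", {
  mp <- motion_params("diffusive", D_true = 0.012, dt = 0.5,
                      n_frames = 10000, seed = 1)
  tr <- simulate_surface_trajectory(mp)
  msd_impl <- mean(tr$step_um[-1]^2)
  arcs <- oracle_diffusion_steps(10000, 0.012, 0.5, 0.75, seed = 99)
  msd_oracle <- mean(arcs^2)
  expected <- 4 * 0.012 * 0.5
  expect_equal(msd_impl, expected, tolerance = 0.05)
  expect_equal(msd_oracle, expected, tolerance = 0.05)
  expect_equal(msd_impl, msd_oracle, tolerance = 0.05)
})

test_that("fixed seed reproduces trajectories and rendered stacks bit for bit", {
  mp <- motion_params("directed", seed = 123)
  expect_identical(simulate_surface_trajectory(mp),
                   simulate_surface_trajectory(mp))
  s1 <- simulate_preset_scene("WT", n_foci = 2, n_frames = 5, seed = 9)
  s2 <- simulate_preset_scene("WT", n_foci = 2, n_frames = 5, seed = 9)
  expect_identical(s1$stack, s2$stack)
  expect_identical(s1$truth, s2$truth)
})

test_that("blank scenes are background plus noise only", {
  sc <- simulate_preset_scene("blank", n_frames = 6, n_cells_blank = 1,
                              seed = 3)
  expect_equal(nrow(sc$truth), 0)
  ## frame mean within 3 SD of the background level (cell body adds a known
  ## offset over its area fraction)
  opt <- sc$optics
  fr <- sc$stack[, , 1]
  body_frac <- pi * (opt$cell_body_level > 0) * (7.5^2) / prod(dim(fr))
  expected <- opt$background_level * (1 + 0) + opt$cell_body_level * body_frac
  expect_lt(abs(mean(fr) - expected), 3 * sd(fr) / sqrt(length(fr)) + 5)
})

test_that("noiseless rendering puts the brightest pixel at the projection", {
  mp <- motion_params("arrested", D_true = 0, seed = 6)
  tr <- simulate_surface_trajectory(mp)
  cells <- data.frame(cell_id = 1, center_x_px = 23.5, center_y_px = 23.5,
                      p_um = 0.75)
  sc <- render_scene(list(tr), cells, optics_params(focal_plane_z = 0),
                     dim_px = c(48, 48), noise = FALSE)
  fr <- sc$stack[, , 1]
  ij <- which(fr == max(fr), arr.ind = TRUE)[1, ]
  expect_lt(abs((ij[2] - 1) - sc$truth$x_px[1]), 1.01)
  expect_lt(abs((ij[1] - 1) - sc$truth$y_px[1]), 1.01)
})

test_that("seeded noisy rendering is localized to 0.15 px by a Gaussian fit", {
  ## one bright focus rendered with noise; the Gaussian fit must land within
  ## 0.15 px of truth, and agree with a center-of-mass oracle applied to the
  ## noiseless image
  th0 <- 0.6
  tr <- structure(data.frame(focus_id = 1L, frame = 0:3, time_min = (0:3) * 0.5,
                             x_um = 0.6 * cos(th0), y_um = 0.6 * sin(th0),
                             z_um = sqrt(0.75^2 - 0.6^2), p_um = 0.75,
                             theta_rad = th0, phi_rad = acos(0.6 / 0.75),
                             step_um = c(NA, 0, 0, 0)),
                  class = c("surface_trajectory", "data.frame"))
  cells <- data.frame(cell_id = 1, center_x_px = 23.5, center_y_px = 23.5,
                      p_um = 0.75)
  opt <- optics_params(peak_photons = 600, cell_body_level = 0,
                       defocus_halfdepth = 1.2)
  scn <- render_scene(list(tr), cells, opt, dim_px = c(48, 48), noise = FALSE)
  sc <- render_scene(list(tr), cells, opt, dim_px = c(48, 48), noise = TRUE,
                     seed = 21)
  expect_gt(sc$truth$amplitude[1], 500)   # accuracy claim applies above 500
  det <- detect_foci(sc$stack[, , 1], list(), k_sigma = 5)
  expect_equal(nrow(det), 1)
  err <- sqrt((det$x_px - sc$truth$x_px[1])^2 + (det$y_px - sc$truth$y_px[1])^2)
  expect_lt(err, 0.15)
  ## center-of-mass oracle on the noiseless frame
  fr <- scn$stack[, , 1] - min(scn$stack[, , 1])
  xs <- matrix(rep(0:47, each = 48), 48, 48)
  ys <- matrix(rep(0:47, 48), 48, 48)
  w <- pmax(fr - 0.05 * max(fr), 0)
  com <- c(sum(xs * w), sum(ys * w)) / sum(w)
  expect_lt(sqrt(sum((com - c(sc$truth$x_px[1], sc$truth$y_px[1]))^2)), 0.1)
})

test_that("foci projecting outside the image are dropped with a warning", {
  tr <- structure(data.frame(focus_id = 1L, frame = 0:1, time_min = c(0, 0.5),
                             x_um = 0.75, y_um = 0, z_um = 0, p_um = 0.75,
                             theta_rad = 0, phi_rad = 0,
                             step_um = c(NA, 0)),
                  class = c("surface_trajectory", "data.frame"))
  cells <- data.frame(cell_id = 1, center_x_px = 2, center_y_px = 2,
                      p_um = 0.75)
  expect_warning(
    sc <- render_scene(list(tr), cells, optics_params(), dim_px = c(9, 9)),
    "outside")
  expect_false(any(sc$truth$rendered))
})

test_that("fixture suite is deterministic and satisfies the step tail bound", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  make_fixture_suite(d1, seed = 42, n_foci = 4, n_frames = 10)
  make_fixture_suite(d2, seed = 42, n_foci = 4, n_frames = 10)
  for (f in c("WT_truth.csv", "exoA_truth.csv", "aglQ_truth.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_true(file.exists(file.path(d1, "manifest.json")))
  ## WT per-frame arc steps obey the drift + 6-sigma diffusion tail bound
  tr <- read.csv(file.path(d1, "WT_truth.csv"))
  tr <- tr[order(tr$focus_id, tr$frame), ]
  for (id in unique(tr$focus_id)) {
    t1 <- tr[tr$focus_id == id, ]
    n <- spherical_to_unit(t1$theta_rad, t1$phi_rad)
    n[, 3] <- sign(t1$z_um) * n[, 3]   # truth keeps the signed hemisphere
    steps <- 0.75 * acos(pmin(1, rowSums(n[-nrow(n), ] * n[-1, ])))
    expect_true(all(steps <= 0.12 * 0.5 + 6 * sqrt(4 * 0.012 * 0.5)))
  }
  ## blank fixture yields no detections downstream
  blank <- read_stack(file.path(d1, "blank_stack.tif"))
  geoms <- segment_cells(apply(blank, c(1, 2), median))
  norm <- normalize_stack(blank, geoms)
  det <- detect_foci(norm[, , 1], geoms)
  expect_equal(nrow(det), 0)
})
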