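## Rendering ground-truth trajectories into synthetic time-lapse stacks.
##
## Foci are drawn as 2D Gaussians at the orthographic projection of their
## surface position; out-of-plane positions are dimmed by a smooth Lorentzian
## attenuation 1 / (1 + ((z - focal_plane_z)/defocus_halfdepth)^2), which
## captures the only property of defocus that matters to a single-plane
## tracker (intensity loss).  The cell body is a dim disk with a PSF-blurred
## edge.  Noise: Poisson photon noise on the full expected signal, then
## additive Gaussian read noise; a slow sinusoidal illumination drift
## multiplies the whole frame over the movie (the fluctuation that
## frame-by-frame background normalization corrects).

#' Optical / camera parameters for the synthetic renderer
#'
#' @param pixel_size µm per pixel.
#' @param psf_sigma Gaussian PSF width, µm (must be >= pixel_size/2 so spots
#'   span more than one pixel).
#' @param peak_photons expected peak amplitude of an in-focus focus, counts.
#' @param background_level mean background, counts.
#' @param background_drift_amplitude fractional amplitude of the slow
#'   sinusoidal illumination drift over the movie (multiplies the whole
#'   frame, as for lamp fluctuations).
#' @param read_noise_sd Gaussian read noise SD, counts.
#' @param defocus_halfdepth |z - focal_plane_z| at which focus intensity
#'   halves, µm.
#' @param focal_plane_z focal plane position along the optical axis relative
#'   to the sphere center, µm (0 = "middle section").
#' @param cell_body_level amplitude of the cell-body disk, counts; emulates
#'   the diffuse membrane fluorescence of the reporter fusion covering the
#'   cell surface, which is what makes the cell outline segmentable in the
#'   fluorescence channel.
#' @return A validated list of class `optics_params`.
#' @export
optics_params <- function(pixel_size = 0.1, psf_sigma = 0.13,
                          peak_photons = 800, background_level = 100,
                          background_drift_amplitude = 0.1,
                          read_noise_sd = 2, defocus_halfdepth = 0.6,
                          focal_plane_z = 0, cell_body_level = 60) {
  stopifnot(pixel_size > 0, psf_sigma >= pixel_size / 2, peak_photons >= 0,
            background_level >= 0, read_noise_sd >= 0, defocus_halfdepth > 0)
  structure(as.list(environment()), class = "optics_params")
}

#' Render trajectories into a noisy image stack
#'
#' @param trajectories list of `surface_trajectory` data.frames (see
#'   [simulate_surface_trajectory]); all must share the sphere radius of the
#'   cell they are assigned to.
#' @param cells data.frame with one row per cell: `cell_id`, `center_x_px`,
#'   `center_y_px`, `p_um`.  Each trajectory is assigned to a cell via the
#'   `cell_id` element of its attribute, or round-robin if absent.
#' @param cell_ids integer vector assigning each trajectory to a row of
#'   `cells` (recycled round-robin when NULL).
#' @param optics an [optics_params] object.
#' @param dim_px image height/width, c(H, W) in pixels.
#' @param noise logical; disable to obtain the clean expected image.
#' @param seed integer seed for the noise draws (NULL: leave RNG alone).
#' @return A list of class `synthetic_scene`: `stack` (H x W x n_frames array
#'   of counts), `truth` (per-frame truth table incl. pixel positions),
#'   `cells`, `optics`.  Foci that project outside the image are dropped from
#'   the affected frames with a warning and marked in the truth table.
#' @export
render_scene <- function(trajectories, cells, optics = optics_params(),
                         cell_ids = NULL, dim_px = c(48, 48), noise = TRUE,
                         seed = NULL) {
  stopifnot(inherits(optics, "optics_params"), length(trajectories) >= 0)
  if (!is.null(seed)) set.seed(seed)
  H <- dim_px[1]; W <- dim_px[2]
  nf <- if (length(trajectories)) max(vapply(trajectories, nrow, 1L)) else
    stop("render_scene needs at least one trajectory to set the frame count; ",
         "use n_frames via a blank trajectory or render_blank_scene")
  if (is.null(cell_ids))
    cell_ids <- rep(seq_len(nrow(cells)), length.out = length(trajectories))

  px <- optics$pixel_size
  sig <- optics$psf_sigma / px                 # PSF sigma in pixels
  half <- max(3L, ceiling(4 * sig))

  ## truth table with pixel-space projection
  truth <- do.call(rbind, lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    ci <- cells[cell_ids[i], ]
    if (abs(tr$p_um[1] - ci$p_um) > 1e-9)
      stop("trajectory radius does not match its cell's sphere radius")
    data.frame(focus_id = i, cell_id = ci$cell_id,
               frame = tr$frame, time_min = tr$time_min,
               x_px = ci$center_x_px + tr$x_um / px,
               y_px = ci$center_y_px - tr$y_um / px,
               z_um = tr$z_um, p_um = tr$p_um,
               theta_rad = tr$theta_rad, phi_rad = tr$phi_rad,
               amplitude = optics$peak_photons /
                 (1 + ((tr$z_um - optics$focal_plane_z) /
                         optics$defocus_halfdepth)^2))
  }))

  oob <- if (is.null(truth) || !nrow(truth)) logical(0) else
    (truth$x_px < 0 | truth$x_px > W - 1 | truth$y_px < 0 | truth$y_px > H - 1)
  if (any(oob)) {
    warning(sum(oob), " focus observation(s) project outside the image and ",
            "are omitted from rendering")
  }
  truth$rendered <- !oob

  ## static cell bodies with a PSF-blurred edge
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  body <- matrix(0, H, W)
  for (k in seq_len(nrow(cells))) {
    rr <- sqrt((xs - cells$center_x_px[k])^2 + (ys - cells$center_y_px[k])^2)
    body <- body + optics$cell_body_level *
      stats::pnorm((cells$p_um[k] / px - rr) / sig)
  }

  stack <- array(0, dim = c(H, W, nf))
  tt <- seq_len(nf) - 1
  drift_t <- 1 + optics$background_drift_amplitude * sin(2 * pi * tt / nf)
  for (f in seq_len(nf)) {
    img <- body + optics$background_level
    rows <- which(truth$frame == f - 1 & truth$rendered & truth$amplitude > 0)
    for (j in rows) {
      x0 <- truth$x_px[j]; y0 <- truth$y_px[j]
      xi <- max(0, floor(x0) - half):min(W - 1, floor(x0) + half + 1)
      yi <- max(0, floor(y0) - half):min(H - 1, floor(y0) + half + 1)
      g <- truth$amplitude[j] *
        outer(exp(-(yi - y0)^2 / (2 * sig^2)), exp(-(xi - x0)^2 / (2 * sig^2)))
      img[yi + 1, xi + 1] <- img[yi + 1, xi + 1] + g
    }
    img <- img * drift_t[f]
    if (noise) {
      img <- stats::rpois(length(img), lambda = img) +
        stats::rnorm(length(img), 0, optics$read_noise_sd)
      img <- matrix(pmin(pmax(round(img), 0), 65535), H, W)
    }
    stack[, , f] <- img
  }
  structure(list(stack = stack, truth = truth, cells = cells,
                 optics = optics),
            class = "synthetic_scene")
}

## ---------------------------------------------------------------------------
## Preset fixture suite

#' Motion presets emulating the experimental conditions
#'
#' "WT": directed transport at v = 0.12 µm/min with surface diffusion
#' D = 0.012 µm^2/min; "exoA": same speeds but with Poisson direction
#' reversals at 2 /min (loss of directionality); "aglQ": arrested foci with
#' residual jitter (D = 0.001 µm^2/min about a fixed anchor); "blank": no
#' foci at all.
#'
#' @param preset preset name.
#' @param n_frames,dt,p_true see [motion_params].
#' @return a [motion_params] object (NULL for "blank").
#' @export
preset_motion <- function(preset = c("WT", "exoA", "aglQ", "blank"),
                          n_frames = 60, dt = 0.5, p_true = 0.75) {
  preset <- match.arg(preset)
  switch(preset,
    WT = motion_params("directed", v_true = 0.12, D_true = 0.012,
                       p_true = p_true, dt = dt, n_frames = n_frames),
    exoA = motion_params("directed_with_reversals", v_true = 0.12,
                         D_true = 0.012, reversal_rate = 2,
                         p_true = p_true, dt = dt, n_frames = n_frames),
    aglQ = motion_params("arrested", D_true = 0.001,
                         p_true = p_true, dt = dt, n_frames = n_frames),
    blank = NULL)
}

#' Lay out cells on a grid and simulate a preset scene
#'
#' @param preset preset name, see [preset_motion].
#' @param n_foci total number of foci (2 per cell; the last cell takes the
#'   remainder).  Ignored for "blank", which renders `n_cells_blank` empty
#'   cells.
#' @param optics an [optics_params] object.
#' @param n_frames,dt,p_true motion parameters.
#' @param foci_per_cell foci placed on each cell.
#' @param n_cells_blank cells rendered for the "blank" preset.
#' @param tile_px size of the square tile allotted to each cell, px.
#' @param noise,seed passed to the renderer; the seed governs both the
#'   trajectories and the noise so a fixed seed gives bit-identical scenes.
#' @return a `synthetic_scene`.
#' @export
simulate_preset_scene <- function(preset, n_foci = 25,
                                  optics = optics_params(), n_frames = 60,
                                  dt = 0.5, p_true = 0.75, foci_per_cell = 2,
                                  n_cells_blank = 4, tile_px = 40,
                                  noise = TRUE, seed = NULL) {
  preset <- match.arg(preset, c("WT", "exoA", "aglQ", "blank"))
  if (!is.null(seed)) set.seed(seed)
  mp <- preset_motion(preset, n_frames = n_frames, dt = dt, p_true = p_true)
  n_cells <- if (preset == "blank") n_cells_blank else
    ceiling(n_foci / foci_per_cell)
  ncol_grid <- ceiling(sqrt(n_cells))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  k <- seq_len(n_cells) - 1
  cells <- data.frame(
    cell_id = seq_len(n_cells),
    center_x_px = (k %% ncol_grid) * tile_px + (tile_px - 1) / 2,
    center_y_px = (k %/% ncol_grid) * tile_px + (tile_px - 1) / 2,
    p_um = p_true)
  dim_px <- c(nrow_grid, ncol_grid) * tile_px

  if (preset == "blank") {
    stack <- render_scene_blank(cells, optics, n_frames, dim_px, noise)
    truth <- data.frame(focus_id = integer(), cell_id = integer(),
                        frame = integer(), time_min = numeric(),
                        x_px = numeric(), y_px = numeric(), z_um = numeric(),
                        p_um = numeric(), theta_rad = numeric(),
                        phi_rad = numeric(), amplitude = numeric(),
                        rendered = logical())
    return(structure(list(stack = stack, truth = truth, cells = cells,
                          optics = optics), class = "synthetic_scene"))
  }

  trajs <- lapply(seq_len(n_foci), function(i) simulate_surface_trajectory(mp, i))
  cell_ids <- rep(seq_len(n_cells), each = foci_per_cell)[seq_len(n_foci)]
  render_scene(trajs, cells, optics, cell_ids = cell_ids, dim_px = dim_px,
               noise = noise, seed = NULL)
}

## blank stack: cells + background + noise only (internal)
render_scene_blank <- function(cells, optics, n_frames, dim_px, noise = TRUE) {
  H <- dim_px[1]; W <- dim_px[2]
  px <- optics$pixel_size
  sig <- optics$psf_sigma / px
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  body <- matrix(0, H, W)
  for (k in seq_len(nrow(cells))) {
    rr <- sqrt((xs - cells$center_x_px[k])^2 + (ys - cells$center_y_px[k])^2)
    body <- body + optics$cell_body_level *
      stats::pnorm((cells$p_um[k] / px - rr) / sig)
  }
  stack <- array(0, dim = c(H, W, n_frames))
  tt <- seq_len(n_frames) - 1
  drift_t <- 1 + optics$background_drift_amplitude * sin(2 * pi * tt / n_frames)
  for (f in seq_len(n_frames)) {
    img <- (body + optics$background_level) * drift_t[f]
    if (noise) {
      img <- stats::rpois(length(img), lambda = img) +
        stats::rnorm(length(img), 0, optics$read_noise_sd)
      img <- matrix(pmin(pmax(round(img), 0), 65535), H, W)
    }
    stack[, , f] <- img
  }
  stack
}

#' Write the full preset fixture suite to disk
#'
#' Writes, for each preset (WT, exoA, aglQ, blank), a 16-bit multi-page TIFF
#' stack and a truth CSV, plus a JSON manifest listing files, seeds and
#' generative parameters.  Runs are deterministic: the same seed reproduces
#' byte-identical truth tables and stacks.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed; each preset uses seed + a fixed offset.
#' @param n_foci,n_frames,optics passed to [simulate_preset_scene].
#' @return the manifest, invisibly (also written as manifest.json).
#' @export
make_fixture_suite <- function(out_dir, seed = 1, n_foci = 25, n_frames = 60,
                               optics = optics_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  presets <- c("WT", "exoA", "aglQ", "blank")
  manifest <- list(seed = seed, presets = list())
  for (i in seq_along(presets)) {
    pr <- presets[i]
    s <- seed + i - 1
    sc <- simulate_preset_scene(pr, n_foci = n_foci, n_frames = n_frames,
                                optics = optics, seed = s)
    stack_file <- file.path(out_dir, paste0(pr, "_stack.tif"))
    truth_file <- file.path(out_dir, paste0(pr, "_truth.csv"))
    cells_file <- file.path(out_dir, paste0(pr, "_cells.csv"))
    write_stack(sc$stack, stack_file)
    utils::write.csv(sc$truth[, c("focus_id", "cell_id", "frame", "time_min",
                                  "x_px", "y_px", "z_um", "p_um",
                                  "theta_rad", "phi_rad")],
                     truth_file, row.names = FALSE)
    utils::write.csv(sc$cells, cells_file, row.names = FALSE)
    manifest$presets[[pr]] <- list(seed = s, stack = basename(stack_file),
                                   truth = basename(truth_file),
                                   cells = basename(cells_file),
                                   n_foci = if (pr == "blank") 0 else n_foci,
                                   n_frames = n_frames)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
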