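## End-to-end pipeline stages: simulate -> track -> analyze.
##
## Each stage reads/writes plain CSV/TIFF/JSON so runs are reproducible from
## the config alone; a manifest records the config, row counts and timings.

#' Pipeline configuration
#'
#' @param pixel_size µm per px.
#' @param frame_interval min between frames.
#' @param k_sigma,min_separation_px detection parameters (NULL separation =
#'   PSF FWHM).
#' @param psf_sigma PSF width, µm.
#' @param max_step linking gate, µm; default 3x the per-frame displacement at
#'   the upper observed transport speed 0.3 µm/min.
#' @param max_gap_frames gap closing: a track interrupted for up to this
#'   many frames (e.g. while crossing an unresolvable partner focus) is
#'   continued rather than restarted (default 2).
#' @param max_lag_fraction MSD lag range.
#' @param min_tracks minimum trajectories for a compliant ensemble MSD
#'   (default 15).
#' @param min_track_length tracks shorter than this are dropped before MSD.
#' @param ambiguity_margin conservative-linking margin, µm (see
#'   [link_tracks]).
#' @param merge_sigma_factor detections whose fitted PSF width exceeds this
#'   multiple of the nominal width are treated as unresolved multi-focus
#'   blobs and discarded before linking (Inf disables).  Two spots blended
#'   below the merge separation broaden the single-Gaussian fit by only
#'   10-40%, while width estimates of clean detections above threshold
#'   scatter by a few percent, so 1.15 separates the two populations.
#' @param seed default seed for seeded stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size = 0.1, frame_interval = 0.5,
                            k_sigma = 5, min_separation_px = NULL,
                            psf_sigma = 0.13,
                            max_step = 3 * 0.3 * frame_interval,
                            max_gap_frames = 2, max_lag_fraction = 0.5,
                            min_tracks = 15, min_track_length = 5,
                            merge_sigma_factor = 1.15,
                            ambiguity_margin = max_step / 4, seed = 1L) {
  stopifnot(pixel_size > 0, frame_interval > 0, k_sigma > 0, psf_sigma > 0,
            max_step > 0, min_tracks >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Simulate a preset fixture
#'
#' @param config a [pipeline_config].
#' @param preset one of "WT", "exoA", "aglQ", "blank".
#' @param out_dir output directory (NULL: keep in memory only).
#' @param n_foci,n_frames scene size.
#' @param seed overrides the config seed.
#' @return the `synthetic_scene`, with files written when `out_dir` is set.
#' @export
run_simulate <- function(config = pipeline_config(), preset, out_dir = NULL,
                         n_foci = 25, n_frames = 60, seed = config$seed) {
  preset <- match.arg(preset, c("WT", "exoA", "aglQ", "blank"))
  optics <- optics_params(pixel_size = config$pixel_size,
                          psf_sigma = config$psf_sigma)
  scene <- simulate_preset_scene(preset, n_foci = n_foci, optics = optics,
                                 n_frames = n_frames,
                                 dt = config$frame_interval, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_stack(scene$stack, file.path(out_dir, paste0(preset, "_stack.tif")))
    utils::write.csv(scene$truth,
                     file.path(out_dir, paste0(preset, "_truth.csv")),
                     row.names = FALSE)
    utils::write.csv(scene$cells,
                     file.path(out_dir, paste0(preset, "_cells.csv")),
                     row.names = FALSE)
    manifest <- list(stage = "simulate",
                     version = as.character(utils::packageVersion("orbitrack")),
                     preset = preset, seed = seed,
                     n_foci = nrow(scene$cells), n_truth_rows = nrow(scene$truth),
                     config = unclass(config))
    jsonlite::write_json(manifest,
                         file.path(out_dir, paste0(preset, "_manifest.json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  scene
}

#' Segment, detect and link a stack into tracks
#'
#' Cells are segmented on the temporal median projection (robust to the
#' moving foci), the stack is normalized for background drift, foci are
#' detected per frame and linked per cell with the orthodromic gate.
#'
#' @param config a [pipeline_config].
#' @param stack an H x W x n_frames array or a TIFF path.
#' @param out_dir optional output directory for geometry/detections/tracks
#'   CSVs.
#' @return list: geometries, detections, tracks, n_cells; empty tables (with
#'   headers) when no cells are found.
#' @export
run_track <- function(config = pipeline_config(), stack, out_dir = NULL) {
  if (is.character(stack)) stack <- read_stack(stack)
  stopifnot(length(dim(stack)) == 3)
  t0 <- proc.time()[3]
  ## low-quantile temporal projection: moving foci (even ones dwelling near
  ## the projected rim) drop out, leaving the static cell bodies
  med <- apply(stack, c(1, 2), stats::quantile, probs = 0.2, names = FALSE)
  geoms <- segment_cells(med, pixel_size = config$pixel_size)
  if (!length(geoms)) {
    message("no cells found in the median projection; returning empty outputs")
    det <- detect_foci(matrix(0, 2, 2) + 1, list())
    tracks <- link_tracks(detections_to_spherical(det, list(),
                                                  config$pixel_size),
                          max_step = config$max_step,
                          dt = config$frame_interval)
    res <- list(geometries = list(), detections = det, tracks = tracks,
                n_cells = 0L)
  } else {
    norm <- normalize_stack(stack, geoms)
    ## subtract the static structure (temporal low-quantile projection of the
    ## normalized stack): cell bodies and fixed background vanish, moving
    ## foci remain, so detection thresholds see only shot noise
    static <- apply(norm, c(1, 2), stats::quantile, probs = 0.2, names = FALSE)
    moving <- norm
    for (f in seq_len(dim(norm)[3])) moving[, , f] <- norm[, , f] - static
    det <- detect_foci_stack(moving, geoms, dt = config$frame_interval,
                             k_sigma = config$k_sigma,
                             min_separation_px = config$min_separation_px,
                             psf_sigma_px = config$psf_sigma / config$pixel_size)
    ## a Gaussian fit much wider than the PSF marks two unresolved foci
    ## blended into one blob; such positions are biased toward neither focus
    ## and are dropped (gap closing bridges the resulting holes)
    if (is.finite(config$merge_sigma_factor) && nrow(det)) {
      wide <- det$fitted == 1 & !is.na(det$sigma) &
        det$sigma > config$merge_sigma_factor *
          (config$psf_sigma / config$pixel_size)
      det <- det[!wide, , drop = FALSE]
    }
    sph <- detections_to_spherical(det, geoms, config$pixel_size)
    tracks <- link_tracks(sph, max_step = config$max_step,
                          dt = config$frame_interval,
                          max_gap_frames = config$max_gap_frames,
                          ambiguity_margin = config$ambiguity_margin)
    res <- list(geometries = geoms, detections = det, tracks = tracks,
                n_cells = length(geoms))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    geometry_table(res$geometries, file.path(out_dir, "geometry.csv"))
    utils::write.csv(res$detections, file.path(out_dir, "detections.csv"),
                     row.names = FALSE)
    utils::write.csv(res$tracks, file.path(out_dir, "tracks.csv"),
                     row.names = FALSE)
    manifest <- list(stage = "track",
                     version = as.character(utils::packageVersion("orbitrack")),
                     n_cells = res$n_cells,
                     n_detections = nrow(res$detections),
                     n_tracks = length(unique(res$tracks$track_id)),
                     wall_s = round(proc.time()[3] - t0, 2),
                     config = unclass(config))
    jsonlite::write_json(manifest, file.path(out_dir, "track_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  res
}

#' Motion analysis of a tracks table
#'
#' Computes instantaneous speeds, the ensemble MSD, the second-order fit
#' (v, D), alpha and the regime call; writes CSV summaries and optional
#' plots.
#'
#' @param config a [pipeline_config].
#' @param tracks a `tracks` data.frame or a tracks CSV path.
#' @param out_dir optional output directory (CSVs + PNG plots).
#' @return list of class `motion_report`: speeds, msd (curve), estimate,
#'   per_track (length/path statistics), n_tracks, below_min_tracks.
#' @export
run_analyze <- function(config = pipeline_config(), tracks, out_dir = NULL) {
  if (is.character(tracks)) tracks <- utils::read.csv(tracks)
  lst <- split_tracks(tracks, min_length = max(3, config$min_track_length))
  if (!length(lst)) stop("no tracks of sufficient length to analyze")
  speeds <- unlist(lapply(lst, instantaneous_speeds), use.names = FALSE)
  per_track <- do.call(rbind, lapply(lst, function(tr) {
    data.frame(track_id = tr$track_id[1], cell_id = tr$cell_id[1],
               n = nrow(tr), duration_min = diff(range(tr$time_min)),
               path_um = max(cumulated_distance(tr)),
               net_um = max(distance_from_origin(tr)),
               median_speed = stats::median(instantaneous_speeds(tr)))
  }))
  msd <- compute_msd(lst, dt = config$frame_interval,
                     max_lag_fraction = config$max_lag_fraction,
                     paper_min_tracks = config$min_tracks)
  est <- classify_motion(fit_msd_directed(msd))
  below <- length(lst) < config$min_tracks
  if (below)
    warning("only ", length(lst), " tracks (< ", config$min_tracks,
            " required for a compliant ensemble MSD)")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(data.frame(speed_um_min = speeds),
                     file.path(out_dir, "speeds.csv"), row.names = FALSE)
    utils::write.csv(per_track, file.path(out_dir, "per_track.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(msd), file.path(out_dir, "msd.csv"),
                     row.names = FALSE)
    fitdf <- data.frame(v_um_min = est$v, D_um2_min = est$D,
                        alpha = est$alpha, regime = est$regime,
                        residual = est$residual, n_tracks = est$n_tracks,
                        below_min_tracks = below)
    utils::write.csv(fitdf, file.path(out_dir, "fit_summary.csv"),
                     row.names = FALSE)
    grDevices::png(file.path(out_dir, "speed_histogram.png"), 600, 450)
    graphics::hist(speeds, breaks = 30, col = "grey70",
                   xlab = "instantaneous speed (um/min)",
                   main = "Instantaneous speeds")
    grDevices::dev.off()
    grDevices::png(file.path(out_dir, "msd_fit.png"), 600, 450)
    graphics::plot(msd$t_min, msd$msd, pch = 16,
                   xlab = "lag time (min)", ylab = "MSD (um^2)",
                   main = sprintf("MSD fit: v = %.3f um/min, D = %.4f um^2/min (%s)",
                                  est$v, est$D, est$regime))
    graphics::curve(4 * est$D * x + est$v^2 * x^2, add = TRUE, col = "red")
    grDevices::dev.off()
  }
  structure(list(speeds = speeds, msd = msd, estimate = est,
                 per_track = per_track, n_tracks = length(lst),
                 below_min_tracks = below), class = "motion_report")
}
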