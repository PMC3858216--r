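## Linking detections into trajectories on the sphere.
##
## Within each cell, consecutive frames are linked by a globally optimal
## one-to-one assignment that minimizes the total orthodromic distance, with
## links longer than max_step forbidden.  Unmatched detections seed new
## tracks; optional gap closing joins a track end to a later track start.

#' Convert planar detections to spherical coordinates on their cell
#'
#' @param detections data.frame from [detect_foci_stack].
#' @param geometries list of `cell_geometry` (must carry fitted `p_um`).
#' @param pixel_size µm per px.
#' @return detections with added columns r_um, theta_rad, phi_rad, p_um and
#'   clamped (TRUE where r > p was clamped to the sphere).
#' @export
detections_to_spherical <- function(detections, geometries, pixel_size = 0.1) {
  if (!nrow(detections)) {
    for (cn in c("r_um", "theta_rad", "phi_rad", "p_um"))
      detections[[cn]] <- numeric(0)
    detections[["clamped"]] <- logical(0)
    return(detections)
  }
  gmap <- stats::setNames(geometries,
                          vapply(geometries, function(g) as.character(g$cell_id), ""))
  out <- detections
  out$r_um <- NA_real_; out$theta_rad <- NA_real_
  out$phi_rad <- NA_real_; out$p_um <- NA_real_; out$clamped <- NA
  for (cidc in unique(as.character(detections$cell_id))) {
    g <- gmap[[cidc]]
    if (is.null(g) || !is.finite(g$p_um)) next
    sel <- detections$cell_id == as.integer(cidc)
    pol <- to_polar(detections$x_px[sel], detections$y_px[sel], g, pixel_size)
    sph <- to_spherical(pol$r, pol$theta, g$p_um)
    out$r_um[sel] <- pol$r
    out$theta_rad[sel] <- sph$theta
    out$phi_rad[sel] <- sph$phi
    out$p_um[sel] <- g$p_um
    out$clamped[sel] <- sph$clamped
  }
  out[!is.na(out$p_um), , drop = FALSE]
}

## exact minimum-cost matching between two small point sets.
## cost: n1 x n2 matrix; entries > gate are forbidden.  Unmatched rows/cols
## incur cost `gate` each (so a link is preferred iff d < gate).  Exact
## branch-and-bound for n1 <= size_exact, greedy gated nearest-neighbor
## beyond.  Ties broken toward lower distance then earlier indices by the
## search order.
.match_frames <- function(cost, gate, size_exact = 9) {
  n1 <- nrow(cost); n2 <- ncol(cost)
  if (n1 == 0 || n2 == 0) return(integer(n1) * NA_integer_)
  if (n1 > size_exact || n2 > size_exact) {
    ## greedy: repeatedly take the globally smallest admissible distance
    assign <- rep(NA_integer_, n1)
    used <- logical(n2)
    repeat {
      cm <- cost
      cm[!is.na(assign), ] <- Inf
      cm[, used] <- Inf
      i <- which.min(cm)
      if (!length(i) || !is.finite(cm[i]) || cm[i] > gate) break
      r <- (i - 1) %% n1 + 1; cl <- (i - 1) %/% n1 + 1
      assign[r] <- cl
      used[cl] <- TRUE
    }
    return(assign)
  }
  best <- list(cost = Inf, assign = rep(NA_integer_, n1))
  assign <- rep(NA_integer_, n1)
  used <- logical(n2)
  unmatched_pen <- gate
  rec <- function(i, acc) {
    if (acc >= best$cost) return()
    if (i > n1) {
      total <- acc + sum(!used) * unmatched_pen
      if (total < best$cost - 1e-12) best <<- list(cost = total, assign = assign)
      return()
    }
    ## try links in increasing distance, then the unmatched option
    ord <- order(cost[i, ])
    for (j in ord) {
      if (used[j] || cost[i, j] > gate) next
      assign[i] <<- j; used[j] <<- TRUE
      rec(i + 1, acc + cost[i, j])
      assign[i] <<- NA_integer_; used[j] <<- FALSE
    }
    rec(i + 1, acc + unmatched_pen)
  }
  rec(1L, 0)
  best$assign
}

#' Link spherical detections into tracks
#'
#' @param sph detections with spherical coordinates
#'   (see [detections_to_spherical]).
#' @param max_step maximum orthodromic step between consecutive frames, µm.
#'   Default 3x the per-frame displacement at the upper observed transport
#'   speed of 0.3 µm/min.
#' @param dt frame interval, min (used for the default gate).
#' @param max_gap_frames close gaps of up to this many missing frames when
#'   joining a track end to a new track start (default 0 = off); the gate
#'   scales with the gap length.
#' @param ambiguity_margin conservative-linking margin, µm: a link is dropped
#'   when a competing head or candidate lies within this cost margin of the
#'   chosen one, because close encounters cannot be disambiguated without a
#'   motion model and a wrong guess scrambles track identities.  Tracks then
#'   break cleanly at the encounter.  Default max_step/4; 0 disables.
#' @return data.frame of class `tracks`: track_id, cell_id, frame, time_min,
#'   p_um, theta_rad, phi_rad, x_px, y_px, intensity, clamped.  Track ids are
#'   deterministic given identical input ordering.
#' @export
link_tracks <- function(sph, max_step = 3 * 0.3 * dt, dt = 0.5,
                        max_gap_frames = 0, ambiguity_margin = max_step / 4) {
  stopifnot(dt > 0, max_step > 0)
  cols <- c("track_id", "cell_id", "frame", "time_min", "p_um", "theta_rad",
            "phi_rad", "x_px", "y_px", "intensity", "clamped")
  if (!nrow(sph)) {
    out <- cbind(data.frame(track_id = integer()), sph[0, ])
    out <- out[intersect(cols, names(out))]
    class(out) <- c("tracks", "data.frame")
    return(out)
  }
  sph <- sph[order(sph$cell_id, sph$frame), , drop = FALSE]
  sph$track_id <- NA_integer_
  next_id <- 1L
  for (cid in unique(sph$cell_id)) {
    rows <- which(sph$cell_id == cid)
    frames <- sort(unique(sph$frame[rows]))
    open <- data.frame(track_id = integer(), row = integer())  # last obs/track
    for (f in frames) {
      cur <- rows[sph$frame[rows] == f]
      if (nrow(open)) {
        prev <- open$row
        gapf <- f - sph$frame[prev]                  # >= 1
        admissible <- gapf <= max_gap_frames + 1
        cost <- outer(seq_along(prev), seq_along(cur),
                      Vectorize(function(i, j)
                        orthodromic_distance(sph$theta_rad[prev[i]],
                                             sph$phi_rad[prev[i]],
                                             sph$theta_rad[cur[j]],
                                             sph$phi_rad[cur[j]],
                                             sph$p_um[prev[i]],
                                             sph$p_um[cur[j]])))
        gates <- max_step * gapf                      # per-row gate
        cost[!admissible, ] <- Inf
        cost_g <- sweep(cost, 1, gates, "/")          # normalize gate to 1
        assign <- .match_frames(cost_g, 1)
        if (ambiguity_margin > 0 && length(cur) + length(prev) > 2) {
          for (i in which(!is.na(assign))) {
            j <- assign[i]
            rival_head <- any(cost[-i, j] <= gates[-i] &
                                cost[-i, j] - cost[i, j] < ambiguity_margin)
            rival_cand <- length(cur) > 1 &&
              any(cost[i, -j] <= gates[i] &
                    cost[i, -j] - cost[i, j] < ambiguity_margin)
            if (isTRUE(rival_head) || isTRUE(rival_cand))
              assign[i] <- NA_integer_
          }
        }
        for (i in seq_along(prev)) {
          if (!is.na(assign[i])) {
            sph$track_id[cur[assign[i]]] <- open$track_id[i]
            open$row[i] <- cur[assign[i]]
          }
        }
        matched_cur <- stats::na.omit(assign)
        new_rows <- setdiff(seq_along(cur), matched_cur)
        for (j in new_rows) {
          sph$track_id[cur[j]] <- next_id
          open <- rbind(open, data.frame(track_id = next_id, row = cur[j]))
          next_id <- next_id + 1L
        }
        ## drop tracks whose last observation is too old to ever link again
        open <- open[f - sph$frame[open$row] <= max_gap_frames, , drop = FALSE]
      } else {
        for (j in seq_along(cur)) {
          sph$track_id[cur[j]] <- next_id
          open <- rbind(open, data.frame(track_id = next_id, row = cur[j]))
          next_id <- next_id + 1L
        }
      }
    }
  }
  out <- sph[order(sph$track_id, sph$frame),
             c("track_id", "cell_id", "frame", "time_min", "p_um",
               "theta_rad", "phi_rad", "x_px", "y_px", "intensity", "clamped")]
  rownames(out) <- NULL
  class(out) <- c("tracks", "data.frame")
  out
}

#' Per-track clamped fraction diagnostic
#' @param tracks a `tracks` data.frame.
#' @return data.frame track_id, n, clamped_fraction.
#' @export
clamped_fraction <- function(tracks) {
  agg <- stats::aggregate(clamped ~ track_id, data = tracks, FUN = mean)
  n <- stats::aggregate(clamped ~ track_id, data = tracks, FUN = length)
  data.frame(track_id = agg$track_id, n = n$clamped,
             clamped_fraction = agg$clamped)
}

#' Split a tracks table into a list of per-track data.frames
#' @param tracks a `tracks` data.frame.
#' @param min_length drop tracks shorter than this many observations.
#' @return named list of data.frames.
#' @export
split_tracks <- function(tracks, min_length = 1) {
  lst <- split(as.data.frame(tracks), tracks$track_id)
  lst[vapply(lst, nrow, 1L) >= min_length]
}
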