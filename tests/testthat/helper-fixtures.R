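## shared fixture builders (all programmatic; no files)

## clean disk image with a PSF-blurred edge on a flat background
disk_image <- function(H = 48, W = 48, cx = 23.5, cy = 23.5, radius = 8,
                       level = 100, amplitude = 60, edge_sigma = 1.3) {
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  rr <- sqrt((xs - cx)^2 + (ys - cy)^2)
  level + amplitude * pnorm((radius - rr) / edge_sigma)
}

## filled ellipse image (half-axes a >= b, rotated by ang, y-up convention)
ellipse_image <- function(H = 64, W = 64, cx = 31.5, cy = 31.5, a = 16, b = 8,
                          ang = 0, level = 100, amplitude = 60,
                          edge_sigma = 1) {
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  dx <- xs - cx
  dy <- -(ys - cy)
  u <- dx * cos(ang) + dy * sin(ang)
  v <- -dx * sin(ang) + dy * cos(ang)
  r <- sqrt((u / a)^2 + (v / b)^2)
  ## signed distance approximation scaled by local radius
  level + amplitude * pnorm((1 - r) * min(a, b) / edge_sigma)
}

## a single Gaussian spot on a flat background
spot_image <- function(H = 40, W = 40, x0 = 20.3, y0 = 17.7, amp = 500,
                       sigma = 1.3, level = 100) {
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  level + amp * exp(-((xs - x0)^2 + (ys - y0)^2) / (2 * sigma^2))
}

## cell_geometry for an ideal circle, built through the package's own
## segmentation on a clean disk image so all fields are consistent
circle_geometry <- function(cx = 23.5, cy = 23.5, radius = 8, H = 48, W = 48,
                            pixel_size = 0.1) {
  img <- disk_image(H, W, cx, cy, radius)
  segment_cells(img, pixel_size = pixel_size)[[1]]
}

## brute-force optimal one-to-one matching by permutation enumeration
## (independent oracle for the linker); returns assignment vector like
## orbitrack:::.match_frames
oracle_match <- function(cost, gate) {
  n1 <- nrow(cost); n2 <- ncol(cost)
  idx_sets <- list(NA_integer_)
  choices <- lapply(seq_len(n1), function(i) c(NA_integer_, seq_len(n2)))
  grid <- do.call(expand.grid, choices)
  best <- NULL; bestc <- Inf
  for (k in seq_len(nrow(grid))) {
    as <- as.integer(unlist(grid[k, ]))
    ok <- TRUE; tot <- 0; used <- logical(n2)
    for (i in seq_len(n1)) {
      j <- as[i]
      if (is.na(j)) { tot <- tot + gate; next }
      if (used[j] || cost[i, j] > gate) { ok <- FALSE; break }
      used[j] <- TRUE; tot <- tot + cost[i, j]
    }
    if (ok) {
      tot <- tot + sum(!used) * gate
      if (tot < bestc - 1e-12) { bestc <- tot; best <- as }
    }
  }
  best
}

## independent tangent-plane Monte-Carlo step oracle for surface diffusion
oracle_diffusion_steps <- function(n, D, dt, p, seed) {
  set.seed(seed)
  arcs <- numeric(n)
  x <- c(0, 0, 1)
  for (i in seq_len(n)) {
    ## build any tangent basis at x
    ref <- if (abs(x[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * x) * x; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(x[2] * e1[3] - x[3] * e1[2], x[3] * e1[1] - x[1] * e1[3],
            x[1] * e1[2] - x[2] * e1[1])
    st <- rnorm(2, 0, sqrt(2 * D * dt))
    xn <- x * p + st[1] * e1 + st[2] * e2
    xn <- xn / sqrt(sum(xn^2))
    arcs[i] <- p * acos(min(1, max(-1, sum(xn * x))))
    x <- xn
  }
  arcs
}
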