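test_that("normalization inverts a multiplicative background drift exactly", {
  base <- disk_image(radius = 8)
  nf <- 8
  stack <- array(0, dim = c(48, 48, nf))
  for (f in 1:nf) stack[, , f] <- base * (1 + 0.2 * sin(f))
  norm <- normalize_stack(stack)
  for (f in 2:nf)
    expect_lt(max(abs(norm[, , f] - norm[, , 1]) / norm[, , 1]), 1e-6)
})

test_that("a single frame is returned unchanged and empty background errors", {
  fr <- disk_image()
  st <- array(fr, dim = c(48, 48, 1))
  norm <- normalize_stack(st)
  expect_equal(norm[, , 1], fr)
  expect_error(normalize_stack(array(0, dim = c(8, 8, 2))), "background")
})

test_that("normalization reduces the CV of focus intensities on a drifting scene", {
  sc <- simulate_preset_scene("aglQ", n_foci = 4, n_frames = 30, seed = 14)
  geoms <- segment_cells(apply(sc$stack, c(1, 2), median))
  norm <- normalize_stack(sc$stack, geoms)
  ## sample raw vs normalized intensity at each focus position over time
  cv <- function(stk) {
    v <- sapply(seq_len(nrow(sc$truth)), function(i) {
      r <- sc$truth[i, ]
      stk[round(r$y_px) + 1, round(r$x_px) + 1, r$frame + 1]
    })
    sd(v) / mean(v)
  }
  expect_lt(cv(norm), cv(sc$stack))
})

test_that("subpixel detection recovers a clean spot to 0.05 px", {
  img <- spot_image(x0 = 20.3, y0 = 17.7, amp = 500)
  det <- detect_foci(img, list(), k_sigma = 3)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_px - 20.3), 0.05)
  expect_lt(abs(det$y_px - 17.7), 0.05)
  expect_equal(det$fitted, 1)
})

test_that("blank frames yield no detections", {
  set.seed(2)
  fr <- matrix(100 + rnorm(48 * 48, 0, 3), 48, 48)
  expect_equal(nrow(detect_foci(fr, list(), k_sigma = 4)), 0)
})

test_that("close spot pairs merge below the separation threshold", {
  psf <- 1.3
  mk <- function(sep) spot_image(x0 = 20 - sep / 2, y0 = 20, amp = 400) +
    spot_image(x0 = 20 + sep / 2, y0 = 20, amp = 400) - 100
  expect_equal(nrow(detect_foci(mk(5 * psf), list())), 2)
  expect_equal(nrow(detect_foci(mk(1 * psf), list())), 1)
})

test_that("detection count is non-increasing in the threshold k_sigma", {
  set.seed(9)
  img <- matrix(100 + rnorm(64 * 64, 0, 5), 64, 64)
  for (k in 1:6) img <- img + spot_image(H = 64, W = 64, x0 = 8 * k + 3,
                                         y0 = 8 * k + 3, amp = 30 * k,
                                         level = 0)
  counts <- sapply(c(1, 2, 3, 5, 8), function(k)
    nrow(detect_foci(img, list(), k_sigma = k)))
  expect_true(all(diff(counts) <= 0))
})

test_that("detections are assigned to the containing cell", {
  g <- circle_geometry()
  img <- spot_image(48, 48, x0 = 26, y0 = 23, amp = 400)
  det <- detect_foci(img, list(g))
  expect_equal(nrow(det), 1)
  expect_equal(det$cell_id, g$cell_id)
  ## a far-away spot is discarded when cells are present
  img2 <- spot_image(48, 48, x0 = 44, y0 = 5, amp = 400)
  det2 <- detect_foci(img2, list(g))
  expect_equal(nrow(det2), 0)
})

test_that("detection on well-separated rendered foci is precise and complete", {
  cfg <- pipeline_config()
  sc <- simulate_preset_scene("WT", n_foci = 8, foci_per_cell = 1, seed = 5)
  res <- run_track(cfg, sc$stack)
  tr <- sc$truth
  det <- res$detections
  tp <- 0; fn <- 0; fp <- 0; errs <- c()
  for (f in unique(tr$frame)) {
    t1 <- tr[tr$frame == f, ]
    d1 <- det[det$frame == f, ]
    used <- rep(FALSE, nrow(d1))
    for (i in seq_len(nrow(t1))) {
      dd <- sqrt((d1$x_px - t1$x_px[i])^2 + (d1$y_px - t1$y_px[i])^2)
      j <- if (nrow(d1)) which.min(ifelse(used, Inf, dd)) else integer(0)
      if (length(j) && dd[j] < 2 && !used[j]) {
        used[j] <- TRUE; tp <- tp + 1; errs <- c(errs, dd[j])
      } else fn <- fn + 1
    }
    fp <- fp + sum(!used)
  }
  expect_gte(tp / (tp + fn), 0.95)
  expect_gte(tp / (tp + fp), 0.95)
  expect_lte(sqrt(mean(errs^2)), 0.15)
})
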