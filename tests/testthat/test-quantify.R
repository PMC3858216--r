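test_that("intensity ratios are bounded and exact on analytic courses", {
  g <- circle_geometry()
  nf <- 10
  base <- disk_image(radius = 8, amplitude = 0)   # flat background 100
  ## constant-intensity cell: ratio identically 1
  stack <- array(rep(disk_image(radius = 8, amplitude = 50), nf),
                 dim = c(48, 48, nf))
  tc <- intensity_ratio_timecourse(stack, list(g), background = 100)
  expect_equal(tc$per_cell$ratio, rep(1, nf))
  ## linear ramp 0 -> max: ratios are t/t_max
  stack <- array(0, dim = c(48, 48, nf))
  for (f in 1:nf) stack[, , f] <- disk_image(radius = 8,
                                             amplitude = 50 * (f - 1) / (nf - 1))
  tc <- intensity_ratio_timecourse(stack, list(g), background = 100)
  expect_equal(tc$per_cell$ratio, (0:(nf - 1)) / (nf - 1), tolerance = 1e-6)
  expect_true(all(tc$per_cell$ratio >= 0 & tc$per_cell$ratio <= 1))
  expect_equal(tc$summary$n, rep(1, nf))
})

test_that("logistic induction curves are recovered within the noise envelope", {
  set.seed(33)
  g <- circle_geometry()
  nf <- 20
  tt <- seq_len(nf)
  truthc <- 1 / (1 + exp(-(tt - 10) / 2))
  stack <- array(0, dim = c(48, 48, nf))
  for (f in 1:nf) stack[, , f] <-
    disk_image(radius = 8, amplitude = 60 * truthc[f]) + rnorm(48^2, 0, 1)
  tc <- intensity_ratio_timecourse(stack, list(g), background = 100)
  expect_lt(max(abs(tc$per_cell$ratio - truthc / max(truthc))), 0.1)
})

test_that("stain area ratios separate covering, absent and loose stains", {
  g <- circle_geometry()
  ## stain exactly covering the cell mask
  stain <- disk_image(radius = 8, amplitude = 80)
  rec <- stain_area_ratio(stain, g, background = 100)
  expect_equal(rec$ratio, 1, tolerance = 0.15)
  expect_false(rec$loose)
  ## no specific stain at all
  rec0 <- stain_area_ratio(matrix(100, 48, 48), g, background = 100)
  expect_equal(rec0$ratio, 0)
  ## a loose-coat halo extending ~20% beyond the mask
  halo <- disk_image(radius = 9.6, amplitude = 80)
  rech <- stain_area_ratio(halo, g, background = 100)
  expect_gt(rech$ratio, 1)
  expect_true(rech$loose)
  expect_gt(rech$ratio, rec$ratio)        # loose coats rank above tight ones
  expect_error(stain_area_ratio(stain, NULL), "mask")
})

test_that("foci are counted per cell with the distribution summary", {
  g1 <- circle_geometry()
  g2 <- circle_geometry(cx = 71.5, H = 48, W = 96)
  g2$cell_id <- 2L
  none <- count_foci_per_cell(data.frame(cell_id = integer()), list(g1, g2))
  expect_equal(none$per_cell$n_foci, c(0L, 0L))
  expect_equal(none$summary$fraction_with_foci, 0)
  det <- data.frame(cell_id = c(1, 1, 1))
  cnt <- count_foci_per_cell(det, list(g1, g2))
  expect_equal(cnt$per_cell$n_foci, c(3L, 0L))
  expect_equal(cnt$summary$fraction_with_foci, 0.5)
  expect_equal(cnt$summary$max, 3L)
  expect_equal(cnt$summary$mean, 1.5)
})

test_that("kymographs reslice static and moving spots as expected stripes", {
  nf <- 20
  H <- 40; W <- 40
  path <- cbind(seq(5, 34, length.out = 30), rep(20, 30))
  ## static spot: constant-position vertical stripe
  stack <- array(rep(spot_image(H, W, x0 = 20, y0 = 20, amp = 300), nf),
                 dim = c(H, W, nf))
  ky <- make_kymograph(stack, path, width_px = 3)
  expect_equal(nrow(ky$image), nf)
  peaks <- apply(ky$image, 1, which.max)
  expect_equal(length(unique(peaks)), 1)
  ## moving spot: stripe slope equals the speed in px/frame
  speed <- 0.8
  stack <- array(0, dim = c(H, W, nf))
  for (f in 1:nf) stack[, , f] <- spot_image(H, W, x0 = 8 + speed * (f - 1),
                                             y0 = 20, amp = 300)
  ky <- make_kymograph(stack, path, width_px = 3)
  peaks <- apply(ky$image, 1, which.max)
  slope <- coef(lm(peaks ~ seq_len(nf)))[2]
  expect_equal(unname(slope), speed, tolerance = 0.1)
  ## empty stack: all-background rows
  stack0 <- array(100, dim = c(H, W, 3))
  ky0 <- make_kymograph(stack0, path)
  expect_true(all(abs(ky0$image - 100) < 1e-9))
  ## path leaving the image is an error
  bad <- cbind(c(30, 50), c(20, 20))
  expect_error(make_kymograph(stack0, bad), "exits")
})

test_that("the default kymograph path follows the brightest orbital ridge", {
  g <- circle_geometry()
  nf <- 30
  stack <- array(0, dim = c(48, 48, nf))
  for (f in 1:nf) {
    a <- 2 * pi * (f - 1) / nf
    stack[, , f] <- disk_image(radius = 8, amplitude = 40) +
      spot_image(48, 48, x0 = 23.5 + 6 * cos(a), y0 = 23.5 - 6 * sin(a),
                 amp = 400, level = 0)
  }
  path <- kymo_default_path(stack, g)
  r <- sqrt((path[, 1] - 23.5)^2 + (path[, 2] - 23.5)^2)
  expect_lt(mean(abs(r - 6)), 1)
})
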