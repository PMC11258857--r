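test_that("rolling ball flattens constants and ignores offsets", {
  const <- matrix(7, 64, 64)
  expect_true(all(rolling_ball_subtract(const, 10) == 0))
  set.seed(5)
  img <- matrix(runif(64 * 64, 100, 200), 64, 64)
  r1 <- rolling_ball_subtract(img, 8)
  r2 <- rolling_ball_subtract(img + 50, 8)
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_true(all(r1 <= img + 1e-12))
  expect_error(rolling_ball_subtract(img, 40), "radius")
  expect_error(rolling_ball_subtract(img, 0), "radius")
})

test_that("rolling ball matches the brute-force reference construction", {
  set.seed(11)
  img <- matrix(runif(40 * 36, 0, 100), 40, 36)
  expect_equal(rolling_ball_subtract(img, 5), oracle_rolling_ball(img, 5))
  expect_equal(gray_open_disc(img, 7),
               oracle_disc_morph(oracle_disc_morph(img, 7, min), 7, max))
})

test_that("rolling ball keeps small bright features and removes vignette", {
  shape <- c(256, 256)
  vig <- vignette_field(shape, 0.5) * 1000
  disk <- matrix(0, shape[1], shape[2])
  cy <- 80; cx <- 160; r_disk <- 8
  for (y in seq_len(shape[1])) for (x in seq_len(shape[2]))
    if ((y - cy)^2 + (x - cx)^2 <= r_disk^2) disk[y, x] <- 500
  img <- vig + disk
  corr <- rolling_ball_subtract(img, 30)
  inside <- disk > 0
  # disk amplitude preserved within 5%
  expect_lt(abs(mean(corr[inside]) - 500) / 500, 0.05)
  # smooth illumination gradient reduced more than 10-fold
  bg_range_before <- diff(range(img[!inside]))
  bg_range_after <- diff(range(corr[!inside]))
  expect_lt(bg_range_after, bg_range_before / 10)
})

test_that("thresholding recovers a clean two-level mask exactly", {
  img <- matrix(100, 64, 64)
  img[20:35, 10:30] <- 200
  mask <- make_cell_mask(img, min_object_px = 16)
  truth <- (img == 200) * 1L
  expect_equal(unclass(mask)[, ], truth, ignore_attr = TRUE)
  prov <- attr(mask, "provenance")
  expect_equal(prov$method, "otsu")
  expect_error(make_cell_mask(matrix(5, 16, 16)), "constant")
})

test_that("small objects are removed and empty masks reported", {
  img <- matrix(100, 64, 64)
  img[10, 10] <- 200  # single-pixel speck
  mask <- make_cell_mask(img, min_object_px = 16)
  expect_equal(sum(mask), 0)
})

test_that("segmentation recovers the simulated mask with Jaccard >= 0.9", {
  tr <- field_ground_truth(1000, 450, 400, 300)
  pair <- simulate_widefield_pair(tr, seed = 23)
  corr <- rolling_ball_subtract(pair$nadh, 50)
  mask <- make_cell_mask(corr)
  truth <- pair$truth$cell_mask_true
  jac <- sum(mask == 1 & truth == 1) / sum(mask == 1 | truth == 1)
  expect_gte(jac, 0.9)
})

test_that("masked means agree with an explicit pixel loop", {
  img <- matrix(10, 10, 10); img[6:10, ] <- 20
  full <- matrix(1L, 10, 10)
  expect_equal(measure_masked_mean(img, full), 15)
  expect_equal(measure_masked_mean(matrix(7, 5, 5), matrix(1L, 5, 5)), 7)
  set.seed(13)
  rimg <- matrix(runif(100), 10, 10)
  rmask <- matrix(rbinom(100, 1, 0.4), 10, 10)
  acc <- 0; nacc <- 0
  for (y in 1:10) for (x in 1:10)
    if (rmask[y, x] == 1) { acc <- acc + rimg[y, x]; nacc <- nacc + 1 }
  expect_equal(measure_masked_mean(rimg, rmask), acc / nacc)
  expect_error(measure_masked_mean(rimg, matrix(0L, 10, 10)), "empty mask")
})

test_that("background ROIs are cell-free, disjoint and deterministic", {
  img <- matrix(100, 96, 96)
  img[40:60, 40:60] <- 200
  mask <- make_cell_mask(img, min_object_px = 16)
  rois <- select_background_rois(mask, n_rois = 3, roi_size = 16)
  rois2 <- select_background_rois(mask, n_rois = 3, roi_size = 16)
  expect_identical(rois, rois2)
  for (i in 1:3) {
    patch <- mask[rois$row[i]:(rois$row[i] + 15), rois$col[i]:(rois$col[i] + 15)]
    expect_equal(sum(patch), 0)
  }
  bg <- measure_background(img, mask, roi_size = 16)
  expect_equal(as.numeric(bg), 100)
  # vignetted noiseless background: estimate lies within the ROI means
  vig <- vignette_field(c(96, 96), 0.3) * 100
  bgv <- measure_background(vig, mask, roi_size = 16)
  expect_gte(as.numeric(bgv), min(attr(bgv, "roi_means")))
  expect_lte(as.numeric(bgv), max(attr(bgv, "roi_means")))
})

test_that("background recovery is within 2% at default noise", {
  tr <- field_ground_truth(1000, 450, 400, 300)
  pair <- simulate_widefield_pair(tr, seed = 29)
  corr <- rolling_ball_subtract(pair$nadh, 50)
  mask <- make_cell_mask(corr)
  bg <- as.numeric(measure_background(pair$nadh, mask))
  # vignetting dims the field; compare against the vignette-weighted truth
  expect_lt(abs(bg / 400 - 1), 0.1)
  tr0 <- field_ground_truth(1000, 450, 400, 300, vignette_strength = 0)
  pair0 <- simulate_widefield_pair(tr0, seed = 29)
  mask0 <- make_cell_mask(rolling_ball_subtract(pair0$nadh, 50))
  bg0 <- as.numeric(measure_background(pair0$nadh, mask0))
  expect_lt(abs(bg0 / 400 - 1), 0.02)
})

test_that("normalized ORR follows the defining formula and its symmetries", {
  expect_equal(normalized_orr(2, 1, 2, 1)$orr, 0.5)
  expect_equal(normalized_orr(3, 1, 1, 1)$orr, 0.75)
  base <- normalized_orr(300, 100, 150, 120)
  for (g in c(0.1, 2, 17)) {
    scaled <- normalized_orr(300 * g, 100 * g, 150, 120)
    expect_equal(scaled$orr, base$orr, tolerance = 1e-12)
  }
  swapped <- normalized_orr(150, 120, 300, 100)
  expect_equal(swapped$orr, 1 - base$orr, tolerance = 1e-12)
  expect_error(normalized_orr(1, 0, 1, 1), "positive")
  expect_error(normalized_orr(1, 1, -2, 1), "positive")
})

test_that("process_fov recovers the true ORR on noiseless fields", {
  tr <- field_ground_truth(1000, 450, 400, 300, vignette_strength = 0)
  pair <- simulate_widefield_pair(tr, noise_model = "none", seed = 37)
  rec <- process_fov(pair)
  expect_lt(abs(rec$orr - tr$orr_true), 1e-3)
  # vignetting cancels in the ratio even though it biases each channel
  trv <- field_ground_truth(1000, 450, 400, 300, vignette_strength = 0.3)
  pv <- simulate_widefield_pair(trv, noise_model = "none", seed = 37)
  recv <- process_fov(pv)
  expect_lt(abs(recv$orr - trv$orr_true), 1e-3)
})

test_that("global per-channel gain leaves the ORR unchanged", {
  tr <- field_ground_truth(1000, 450, 400, 300, vignette_strength = 0)
  pair <- simulate_widefield_pair(tr, noise_model = "none", seed = 41)
  rec <- process_fov(pair)
  doubled <- pair
  doubled$fad <- pair$fad * 2
  rec2 <- process_fov(doubled)
  expect_lt(abs(rec2$orr - rec$orr), 1e-3)
  halved <- pair
  halved$nadh <- pair$nadh * 0.5
  rec3 <- process_fov(halved)
  expect_lt(abs(rec3$orr - rec$orr), 1e-3)
})

test_that("channel swap maps ORR to its complement", {
  tr <- field_ground_truth(1000, 450, 400, 300, vignette_strength = 0)
  pair <- simulate_widefield_pair(tr, noise_model = "none", seed = 43)
  rec <- process_fov(pair)
  swapped <- pair
  swapped$nadh <- pair$fad; swapped$fad <- pair$nadh
  # the mask comes from the (now dimmer-contrast) FAD geometry, but the
  # noiseless two-level structure still separates cleanly
  rec2 <- process_fov(swapped)
  expect_equal(rec2$orr, 1 - rec$orr, tolerance = 1e-6)
})

test_that("failures carry the name of the failing stage", {
  tr <- field_ground_truth(1000, 450, 400, 300)
  pair <- simulate_widefield_pair(tr, noise_model = "none", seed = 3)
  pair$nadh <- matrix(100, 192, 192)  # no cells in the masking channel
  expect_error(process_fov(pair), "make_cell_mask")
})

test_that("ORR stays in (0,1) across random positive-intensity fields", {
  set.seed(19)
  for (i in 1:20) {
    vals <- runif(4, 1, 1000)
    orr <- normalized_orr(vals[1], vals[2], vals[3], vals[4])$orr
    expect_gt(orr, 0); expect_lt(orr, 1)
  }
})
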