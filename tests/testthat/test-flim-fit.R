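test_that("noiseless model output is recovered from perturbed inits", {
  irf <- std_irf()
  truth <- list(amplitude = 40, tau1 = 420, tau2 = 2600, a1 = 0.65,
                offset = 0.5)
  d <- model_decay(truth$tau1, truth$tau2, truth$a1,
                   amplitude = truth$amplitude, offset = truth$offset,
                   irf = irf)
  for (f in c(0.8, 1.2)) {
    fp <- fit_pixel(d, irf,
                    init = list(tau1 = truth$tau1 * f,
                                tau2 = truth$tau2 * f,
                                a1 = min(truth$a1 * f, 1),
                                amplitude = truth$amplitude * f,
                                offset = truth$offset))
    expect_true(fp$valid)
    expect_equal(fp$tau1, truth$tau1, tolerance = 1e-3)
    expect_equal(fp$tau2, truth$tau2, tolerance = 1e-3)
    expect_equal(fp$a1, truth$a1, tolerance = 1e-3)
  }
})

test_that("pure-background decays are flagged, not fitted", {
  irf <- std_irf()
  expect_false(fit_pixel(rep(0, 256), irf)$valid)
  set.seed(2)
  flat <- rpois(256, 3)  # constant offset, no decay component
  fp <- fit_pixel(flat, irf)
  expect_true(!fp$valid || fp$amplitude * 256 < sum(flat) * 0.1)
})

test_that("single-pixel Monte Carlo recovery stays within 10% at 5000 photons", {
  irf <- std_irf()
  tr <- decay_ground_truth(400, 2500, 0.7, photons_target = 5000)
  mu <- redoxscreen:::expected_decay(tr, irf)
  fits <- withr::with_seed(31, {
    lapply(1:60, function(i) fit_pixel(rpois(256, mu), irf))
  })
  fits <- do.call(rbind, fits)
  expect_gt(mean(fits$valid), 0.95)
  ok <- fits[fits$valid, ]
  expect_lt(abs(median(ok$tau1) / 400 - 1), 0.10)
  expect_lt(abs(median(ok$tau2) / 2500 - 1), 0.10)
  expect_lt(abs(median(ok$a1) / 0.7 - 1), 0.10)
})

test_that("fit_cube fits only masked, photon-rich pixels", {
  irf <- std_irf()
  # all-zero cube: nothing to fit
  zero <- decay_cube(array(0, c(8, 8, 256)), bin_width = irf$bin_width)
  expect_warning(res0 <- fit_cube(zero, irf, align_irf = FALSE,
                                  mask = matrix(0L, 8, 8)), "empty mask")
  expect_equal(sum(res0$valid), 0)

  tr <- decay_ground_truth(400, 2500, 0.7, photons_target = 300)
  cube <- simulate_decay_cube(tr, irf, c(12, 12), seed = 8)
  # infinite threshold excludes every pixel
  res_inf <- fit_cube(cube, irf, photon_threshold = Inf)
  expect_equal(sum(res_inf$valid), 0)
  # half-mask: no valid pixels outside it
  mask <- matrix(0L, 12, 12); mask[, 1:6] <- 1L
  res <- fit_cube(cube, irf, mask = mask, photon_threshold = 500)
  expect_equal(sum(res$valid[, 7:12]), 0)
  expect_gt(sum(res$valid[, 1:6]), 0)
})

test_that("tau_m identity and fraction normalization hold on valid pixels", {
  irf <- std_irf()
  tr <- decay_ground_truth(400, 2500, 0.7, photons_target = 400)
  cube <- simulate_decay_cube(tr, irf, c(12, 12), seed = 4)
  res <- fit_cube(cube, irf)
  v <- res$valid
  expect_gt(sum(v), 0)
  expect_equal(res$tau_m[v], res$a1[v] * res$tau1[v] + res$a2[v] * res$tau2[v])
  expect_equal(res$a1[v] + res$a2[v], rep(1, sum(v)))
  # invalid pixels are NA, never silent zeros
  expect_true(all(is.na(res$tau_m[!v])))
})

test_that("homogeneous cube recovers the true mean lifetime", {
  irf <- std_irf()
  tr <- decay_ground_truth(400, 2500, 0.7, photons_target = 300)
  cube <- simulate_decay_cube(tr, irf, c(16, 16), seed = 21)
  res <- fit_cube(cube, irf, photon_threshold = 1000)
  interior <- res$valid[2:15, 2:15]
  expect_gt(mean(interior), 0.95)
  tau_m_true <- 0.7 * 400 + 0.3 * 2500
  expect_lt(abs(mean(res$tau_m[res$valid]) / tau_m_true - 1), 0.05)
})

test_that("monoexponential data pushes tau_m to tau1", {
  irf <- std_irf()
  tr <- decay_ground_truth(tau1 = 800, tau2 = 3000, a1 = 1,
                           photons_target = 2000)
  cube <- simulate_decay_cube(tr, irf, c(8, 8), seed = 12)
  res <- fit_cube(cube, irf, photon_threshold = 1000)
  expect_gt(sum(res$valid), 0)
  expect_lt(abs(median(res$tau_m[res$valid]) / 800 - 1), 0.10)
})

test_that("aggregation over labels conserves the global mean", {
  irf <- std_irf()
  tr <- decay_ground_truth(400, 2500, 0.7, photons_target = 400)
  cube <- simulate_decay_cube(tr, irf, c(10, 10), seed = 6)
  res <- fit_cube(cube, irf)
  # single label covering everything reproduces the global mean
  all_lab <- matrix(1L, 10, 10)
  agg <- aggregate_flim(res, all_lab)
  expect_equal(agg$mean_tau_m, mean(res$tau_m[res$valid]))
  # random partition: pixel-weighted label means reassemble the global mean
  set.seed(3)
  labs <- matrix(sample(1:3, 100, replace = TRUE), 10, 10)
  agg3 <- aggregate_flim(res, labs)
  total <- sum(agg3$mean_tau_m * agg3$n_valid, na.rm = TRUE) /
    sum(agg3$n_valid)
  expect_equal(total, mean(res$tau_m[res$valid]))
  # empty labels produce NA rows, not dropped rows
  labs2 <- matrix(1L, 10, 10); labs2[1, 1] <- 2L
  res2 <- res; res2$valid[1, 1] <- FALSE; res2$tau_m[1, 1] <- NA
  agg2 <- aggregate_flim(res2, labs2)
  expect_equal(nrow(agg2), 2)
  expect_true(is.na(agg2$mean_tau_m[agg2$label == 2]))
})

test_that("two constant disjoint regions aggregate to their own values", {
  res <- structure(list(
    tau_m = matrix(c(rep(900, 8), rep(1400, 8)), 4, 4),
    a2 = matrix(0.3, 4, 4), a1 = matrix(0.7, 4, 4),
    tau1 = matrix(400, 4, 4), tau2 = matrix(2500, 4, 4),
    valid = matrix(TRUE, 4, 4)), class = "flim_fit_result")
  labs <- matrix(c(rep(1L, 8), rep(2L, 8)), 4, 4)
  agg <- aggregate_flim(res, labs)
  expect_equal(agg$mean_tau_m, c(900, 1400))
  expect_equal(agg$median_tau_m, c(900, 1400))
})
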