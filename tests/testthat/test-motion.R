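test_that("PIV recovers constructed shifts to subpixel accuracy", {
  img <- bead_image()
  ## integer shift
  vf <- keratrack:::piv_core(img, keratrack:::shift_mat(img, 0, 3), 32, 0.5)
  expect_lte(max(abs(vf$u[vf$valid] - 3)), 0.05)
  expect_lte(max(abs(vf$v[vf$valid])), 0.05)
  ## subpixel shift
  sub <- keratrack:::fourier_shift(img, 2.6, 0)
  vf2 <- keratrack:::piv_core(img, sub, 32, 0.5)
  expect_lt(mean(abs(vf2$u[vf2$valid] - 2.6)), 0.2)
  ## normalized correlation: invariant to global intensity scaling
  vf3 <- keratrack:::piv_core(img, sub * 2, 32, 0.5)
  both <- vf2$valid & vf3$valid
  expect_lt(max(abs(vf3$u[both] - vf2$u[both])), 0.05)
  ## identical frames: static
  vf4 <- keratrack:::piv_core(img, img, 32, 0.5)
  expect_lt(max(abs(c(vf4$u[vf4$valid], vf4$v[vf4$valid]))), 0.02)
  ## featureless window flagged invalid, not zero
  flat <- matrix(5, 64, 64)
  vf5 <- keratrack:::piv_core(flat, flat, 32, 0.5)
  expect_false(any(vf5$valid))
  expect_true(all(is.na(vf5$u)))
  expect_error(keratrack:::piv_core(img, img, 8, 0.5), ">= 16")
})

test_that("flow estimator is unbiased across shift magnitudes", {
  img <- bead_image(seed = 17)
  for (s in c(0.5, 1.5, 3, 5)) {
    sh <- keratrack:::fourier_shift(img, s, 0)
    v <- keratrack:::piv_core(img, sh, 32, 0.5)
    expect_lt(abs(mean(v$u[v$valid]) - s), 0.1)
  }
})

test_that("flow fields carry physical units and respect the mask", {
  img <- bead_image(seed = 3)
  sh <- keratrack:::fourier_shift(img, 3, 0)     # 3 px
  mask <- matrix(FALSE, 256, 256); mask[, 1:128] <- TRUE
  vf <- compute_flow_field(img, sh, 32, 0.5, mask = mask, dt_min = 2,
                           pixel_size_um = 0.1)
  ## 3 px * 0.1 um / 2 min
  expect_lt(abs(mean(vf$u[vf$valid]) - 0.15), 0.01)
  ## windows outside the mask are invalid
  right <- rep(vf$x_px, each = length(vf$y_px)) > 128
  expect_false(any(vf$valid[matrix(right, nrow(vf$u))]))
})

test_that("mean flow rate matches simulated uniform flow and radial profiles rise outward", {
  sc <- disc_scene(n_curves = 30, seed = 7, margin_um = 3)
  fs <- simulate_flow_series(sc, 0.3, n_frames = 4, dt_min = 1, mode = "uniform")
  flds <- lapply(1:3, function(t)
    compute_flow_field(fs$stack$voxels[t, , , ], fs$stack$voxels[t + 1, , , ],
                       32, 0.5, mask = sc$geometry$mask, dt_min = 1,
                       pixel_size_um = PIXEL))
  mfr <- mean_flow_rate(flds, mask = sc$geometry$mask,
                        center_px = sc$geometry$center_px)
  expect_lt(abs(mfr$mean_rate_um_min - 0.3) / 0.3, 0.1)
  expect_gt(mfr$n_valid, 0)

  ## peripheral flow scene: monotone increasing radial profile
  fsr <- simulate_flow_series(sc, 0.5, n_frames = 3, dt_min = 1, mode = "radial")
  inner <- keratrack:::erode_mask(sc$geometry$mask, 17)
  fldr <- lapply(1:2, function(t)
    compute_flow_field(fsr$stack$voxels[t, , , ], fsr$stack$voxels[t + 1, , , ],
                       32, 0.5, mask = inner, dt_min = 1, pixel_size_um = PIXEL))
  prof <- mean_flow_rate(fldr, center_px = sc$geometry$center_px,
                         n_radial_bins = 5)$radial_profile
  rates <- prof$rate_um_min[!is.na(prof$rate_um_min)]
  expect_true(all(diff(rates) > 0))

  ## zero flow: at the noise floor
  fs0 <- simulate_flow_series(sc, 0, n_frames = 3, dt_min = 1, mode = "uniform")
  fl0 <- compute_flow_field(fs0$stack$voxels[1, , , ], fs0$stack$voxels[2, , , ],
                            32, 0.5, mask = sc$geometry$mask, dt_min = 1,
                            pixel_size_um = PIXEL)
  expect_lt(mean_flow_rate(list(fl0))$mean_rate_um_min, 0.05)
})

test_that("rotation rate recovers rigid rotation with the right sign", {
  sc <- disc_scene(n_curves = 30, seed = 3, margin_um = 2)
  fs <- simulate_flow_series(sc, mode = "rotation", omega_deg_per_frame = 2,
                             n_frames = 4, dt_min = 3)
  rot <- rotation_rate(fs, center_px = sc$geometry$center_px, dt_min = 3,
                       mask = sc$geometry$mask)
  expect_lt(abs(rot$omega_deg_h - 40) / 40, 0.05)
  expect_identical(rot$sign, 1)
  ## window-size independence within 5%
  rot64 <- rotation_rate(fs, center_px = sc$geometry$center_px, dt_min = 3,
                         window_px = 64, mask = sc$geometry$mask)
  expect_lt(abs(rot64$omega_deg_h - rot$omega_deg_h) / abs(rot$omega_deg_h), 0.05)
  ## time reversal flips the sign, magnitude preserved
  rev <- fs; rev$stack$voxels <- fs$stack$voxels[4:1, , , ]
  rrev <- rotation_rate(rev, center_px = sc$geometry$center_px, dt_min = 3,
                        mask = sc$geometry$mask)
  expect_identical(rrev$sign, -1)
  expect_lt(abs(abs(rrev$omega_deg_h) - abs(rot$omega_deg_h)) /
              abs(rot$omega_deg_h), 0.05)
  ## static series
  fs0 <- simulate_flow_series(sc, 0, n_frames = 3, dt_min = 3, mode = "uniform")
  r0 <- rotation_rate(fs0, center_px = sc$geometry$center_px, dt_min = 3,
                      mask = sc$geometry$mask)
  expect_lt(abs(r0$omega_deg_h), 1)
  ## center outside the mask is rejected
  expect_error(rotation_rate(fs, center_px = c(2, 2), dt_min = 3,
                             mask = sc$geometry$mask), "outside")
})
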