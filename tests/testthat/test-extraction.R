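test_that("ridge enhancement is normalized, zero on flat images, scale invariant", {
  flat <- image_stack(matrix(7, 64, 64))
  expect_true(all(ridge_enhance(flat)$response == 0))

  mp <- make_micropattern("disc", 25, PIXEL, c(128, 128))
  sc <- synthetic_scene(mp, network = line_truth(20, 100, 60),
                        optics = list(amplitude = 100),
                        noise = list(poisson = FALSE, read_sigma = 0), seed = 1)
  stk <- render_network_stack(sc, add_noise = FALSE)
  r <- ridge_enhance(stk)
  expect_true(all(r$response >= 0 & r$response <= 1))
  ## argmax of the composite response sits on the centerline
  R <- apply(r$response, c(2, 3), max)
  for (x in seq(30, 90, by = 15))
    expect_lte(abs(which.max(R[, x + 1]) - 1 - 60), 1)
  ## intensity scaling drops out after normalization
  stk10 <- stk; stk10$voxels <- stk10$voxels * 10
  expect_equal(ridge_enhance(stk10)$response, r$response, tolerance = 1e-12)
})

test_that("centerline extraction recovers constructed filaments", {
  mp <- make_micropattern("disc", 25, PIXEL, c(128, 128))
  ## blank stack: no segments
  blank <- image_stack(array(0, c(1, 64, 64)))
  expect_length(extract_centerlines(ridge_enhance(blank)), 0)

  ## one straight filament at SNR ~10: one segment, endpoints within 2 px
  sc <- synthetic_scene(mp, network = line_truth(20, 100, 60),
                        optics = list(amplitude = 80), seed = 1)
  den <- denoise_stack(render_network_stack(sc), "gaussian", sigma_px = 1)
  segs <- extract_centerlines(ridge_enhance(den), tau = 0.008, spacing_px = 2,
                              min_length_px = 10, intensity_stack = den)
  expect_length(segs, 1)
  V <- segs[[1]]$vertices / PIXEL
  ends_x <- sort(c(V[1, 1], V[nrow(V), 1]))
  expect_lt(abs(ends_x[1] - 20), 2)
  expect_lt(abs(ends_x[2] - 100), 2)
  expect_lt(max(abs(V[, 2] - 60)), 1.5)
  ## vertex spacing respects the configured resampling
  d <- sqrt(rowSums(diff(V)^2))
  expect_lte(max(d), 2 * 2 + 1e-6)

  ## two parallel filaments 10 px apart stay separate
  net2 <- line_truth(20, 100, 55)
  net2$curves[[2]] <- cbind(seq(20, 100, length.out = 200) * PIXEL,
                            rep((55 + 10) * PIXEL, 200), rep(1, 200))
  net2$profiles[[2]] <- rep(1, 200)
  net2$amplitude <- c(1, 1)
  sc2 <- synthetic_scene(mp, network = net2, optics = list(amplitude = 80),
                         seed = 2)
  den2 <- denoise_stack(render_network_stack(sc2), "gaussian", sigma_px = 1)
  segs2 <- extract_centerlines(ridge_enhance(den2), intensity_stack = den2)
  expect_length(segs2, 2)
  ys <- sort(vapply(segs2, function(s) mean(s$vertices[, 2]) / PIXEL, 0))
  expect_lt(abs(ys[1] - 55), 1.5)
  expect_lt(abs(ys[2] - 65), 1.5)
})

test_that("extraction meets the recovery contract on noisy networks", {
  sc <- disc_scene(n_curves = 15, amplitude = 35, seed = 21)
  den <- denoise_stack(render_network_stack(sc), "gaussian", sigma_px = 1)
  segs <- extract_centerlines(ridge_enhance(den), intensity_stack = den)
  rec <- centerline_recovery(sc$network$curves, segs, PIXEL, tol_px = 1.5)
  expect_gte(rec$recall, 0.8)
  expect_gte(rec$precision, 0.8)
  ## resampling preserves arc length within 2%
  for (s in segs[1:min(5, length(segs))]) {
    res <- keratrack:::resample_polyline(s$vertices, 0.1)
    expect_lt(abs(keratrack:::polyline_arclength(res) -
                    segment_arclength(s)) / segment_arclength(s), 0.02)
  }
})

test_that("snake text files round-trip through the documented dialect", {
  fixture <- system.file("extdata", "example_snakes.txt", package = "keratrack")
  segs <- read_tsoax_snakes(fixture, pixel_size_um = 0.5, z_step_um = 1)
  expect_length(segs, 2)
  expect_identical(vapply(segs, `[[`, 0L, "segment_id"), c(0L, 1L))
  expect_equal(segs[[1]]$vertices[1, ], c(10.5 * 0.5, 20 * 0.5, 1 * 1))
  expect_equal(nrow(segs[[2]]$vertices), 4)
  expect_equal(segs[[1]]$mean_intensity, mean(c(100, 110, 105)))
  expect_equal(nrow(attr(segs, "junctions_um")), 1)

  ## empty file
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), p)
  expect_length(read_tsoax_snakes(p), 0)

  ## truncated vertex row: error naming the line
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("snake 0", "0 1.0 2.0 0.0 50", "1 3.0"), bad)
  expect_error(read_tsoax_snakes(bad), "line 3")
})
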