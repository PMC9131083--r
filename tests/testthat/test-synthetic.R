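test_that("simulated networks stay inside the mask and are seed-deterministic", {
  mp <- make_micropattern("D", 47, PIXEL, c(256, 256))
  net <- simulate_filament_network(mp, n_curves = 50, seed = 7)
  expect_length(net$curves, 50)
  for (P in net$curves) {
    xp <- round(P[, 1] / PIXEL) + 1; yp <- round(P[, 2] / PIXEL) + 1
    expect_true(all(mp$mask[cbind(yp, xp)]))
  }
  expect_identical(net, simulate_filament_network(mp, n_curves = 50, seed = 7))
  ## empty network and empty-mask error
  expect_length(simulate_filament_network(mp, n_curves = 0, seed = 1)$curves, 0)
  empty <- mp; empty$mask[] <- FALSE
  expect_error(simulate_filament_network(mp, 5, mask = empty$mask), "empty")
})

test_that("rendering is nonnegative with ridges on the centerlines", {
  sc <- disc_scene(n_curves = 0, seed = 1, diameter = 25, frame = 128)
  sc$network$particles <- matrix(numeric(0), 0, 3)
  sc$optics$background <- 0
  sc$noise <- list(poisson = FALSE, read_sigma = 0)
  expect_true(all(render_network_stack(sc)$voxels == 0))

  ## single straight noiseless curve: intensity maxima within 1 px of truth
  mp <- make_micropattern("disc", 25, PIXEL, c(128, 128))
  net <- line_truth(20, 100, 60)
  sc2 <- synthetic_scene(mp, network = net, optics = list(amplitude = 100),
                         noise = list(poisson = FALSE, read_sigma = 0), seed = 1)
  stk <- render_network_stack(sc2, add_noise = FALSE)
  proj <- apply(stk$voxels, c(2, 3), max)
  for (x in seq(25, 95, by = 10)) {
    ymax <- which.max(proj[, x + 1]) - 1
    expect_lte(abs(ymax - 60), 1)
  }
})

test_that("Poisson rendering is unbiased at a curve voxel", {
  mp <- make_micropattern("disc", 12, 0.25, c(64, 64))
  n <- 150
  net <- structure(list(
    curves = list(cbind(seq(12, 50, length.out = n) * 0.25,
                        rep(31 * 0.25, n), rep(0, n))),
    profiles = list(rep(1, n)), amplitude = 1,
    particles = matrix(numeric(0), 0, 3), seed = 1L),
    class = "filament_truth")
  sc <- synthetic_scene(mp, network = net,
                        optics = list(amplitude = 60, nz = 1L),
                        noise = list(poisson = TRUE, read_sigma = 0), seed = 1)
  clean <- render_network_stack(sc, add_noise = FALSE)
  vox <- c(1, 32, 32)  # on the line
  mu <- clean$voxels[vox[1], vox[2], vox[3]]
  draws <- vapply(1:100, function(i) {
    s <- sc; s$seed <- i
    render_network_stack(s)$voxels[vox[1], vox[2], vox[3]]
  }, 0)
  se <- sqrt(mu / 100)
  expect_lt(abs(mean(draws) - mu), 3 * se + 1e-9)
})

test_that("flow series honors the prescribed motion and seed", {
  sc <- disc_scene(n_curves = 10, seed = 4, diameter = 25, frame = 128,
                   margin_um = 3)
  ## v = 0: all frames identical in noiseless mode
  fs0 <- simulate_flow_series(sc, 0, n_frames = 3, dt_min = 1,
                              mode = "uniform", add_noise = FALSE)
  expect_identical(fs0$stack$voxels[1, , , ], fs0$stack$voxels[3, , , ])
  ## uniform ground truth table
  fs <- simulate_flow_series(sc, 0.3, n_frames = 4, dt_min = 1, mode = "uniform")
  expect_equal(fs$truth$dx_um, c(0, 0.3, 0.6, 0.9))
  expect_identical(fs$stack$voxels,
                   simulate_flow_series(sc, 0.3, n_frames = 4, dt_min = 1,
                                        mode = "uniform")$stack$voxels)
  ## speed that drives curves out of the mask flags clipping
  expect_warning(fsc <- simulate_flow_series(sc, 8, n_frames = 4, dt_min = 1,
                                             mode = "uniform"), "frozen")
  expect_true(fsc$clipped)
})

test_that("traction scenes satisfy the forward-model consistency contract", {
  mp <- make_micropattern("disc", 40, PIXEL, c(256, 256))
  patches <- traction_dipole(c(29, 29), axis_deg = 0, separation_um = 24,
                             amplitude_pa = 500, width_um = 8)
  sc <- synthetic_scene(mp, truth_traction = patches, seed = 9)
  ts <- simulate_traction_scene(sc, add_noise = FALSE)
  ## bead displacements equal the forward solution at bead positions
  ux <- keratrack:::bilinear(ts$truth$ux, ts$beads$x_px, ts$beads$y_px)
  expect_lt(max(abs(ux - ts$beads$ux_um)) / PIXEL, 0.05)
  ## determinism
  ts2 <- simulate_traction_scene(sc, add_noise = FALSE)
  expect_identical(ts$reference$voxels, ts2$reference$voxels)
  expect_identical(ts$stressed$voxels, ts2$stressed$voxels)
  ## zero traction: stressed identical to reference (noiseless)
  sc0 <- sc; sc0$truth_traction <- patches[0, ]
  ts0 <- simulate_traction_scene(sc0, add_noise = FALSE)
  expect_identical(ts0$reference$voxels, ts0$stressed$voxels)
  ## unbalanced traction is rejected
  bad <- patches; bad$tx_pa <- abs(bad$tx_pa)
  scb <- sc; scb$truth_traction <- bad
  expect_error(simulate_traction_scene(scb), "force-balanced")
})

test_that("generated traction fields are force balanced", {
  mp <- make_micropattern("disc", 47, PIXEL, c(256, 256))
  sc <- simulate_cell_group(mp, n_cells = 4, seed = 3)
  tg <- keratrack:::traction_patch_grids(sc$truth_traction, 256, 256, PIXEL)
  tot <- sum(sqrt(tg$tx^2 + tg$ty^2))
  expect_lt(abs(sum(tg$tx)), 1e-6 * tot)
  expect_lt(abs(sum(tg$ty)), 1e-6 * tot)
})

test_that("ablation removes exactly the chosen cell and scales tractions", {
  mp <- make_micropattern("disc", 47, PIXEL, c(256, 256))
  sc <- simulate_cell_group(mp, n_cells = 4, curves_per_cell = 8, seed = 5)
  n_cell1 <- length(sc$cells$curve_index[[1]])
  post <- simulate_ablation(sc, 1, 0.8)
  expect_length(post$network$curves, length(sc$network$curves) - n_cell1)
  expect_equal(post$truth_traction$tx_pa, sc$truth_traction$tx_pa * 0.8)
  ## untouched cells keep their exact curves
  for (i in 2:4) {
    pre_curves <- sc$network$curves[sc$cells$curve_index[[i]]]
    post_curves <- post$network$curves[post$cells$curve_index[[i]]]
    expect_identical(pre_curves, post_curves)
  }
  ## identity case
  same <- simulate_ablation(sc, 0, 1)
  expect_identical(same$network, sc$network)
  expect_identical(same$truth_traction, sc$truth_traction)
  expect_error(simulate_ablation(sc, 9, 0.8), "ablated_cell_index")
  expect_error(simulate_ablation(sc, 1, 0), "traction_scale")
})
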