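test_that("Green's tensor matches the closed form and its symmetries", {
  E <- 11000; nu <- 0.5
  kx <- 0.3; ky <- 0.3
  G <- greens_tensor(kx, ky, E, nu)
  k <- sqrt(kx^2 + ky^2)
  pref <- 2 * (1 + nu) / (E * k^3)
  expect_equal(G[1, 2], -nu * kx * ky * pref)
  expect_equal(G[1, 1], pref * ((1 - nu) * k^2 + nu * ky^2))
  expect_identical(G[1, 2], G[2, 1])
  ## overall 1/k scaling
  expect_equal(greens_tensor(2 * kx, 2 * ky, E, nu), G / 2)
  ## rotation equivariance (isotropy)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  kv <- c(0.4, -0.2)
  kr <- t(R) %*% kv
  expect_lt(max(abs(R %*% greens_tensor(kr[1], kr[2], E, nu) %*% t(R) -
                      greens_tensor(kv[1], kv[2], E, nu))), 1e-12)
  expect_error(greens_tensor(0, 0), "k = 0")
})

test_that("forward displacement is linear, localized, zero for zero traction", {
  n <- 64; h <- 1
  z <- matrix(0, n, n)
  u0 <- forward_displacement(z, z, h)
  expect_true(all(u0$ux == 0) && all(u0$uy == 0))
  d <- dipole_grids(n = 64, h = 1, width_um = 3, sep_um = 12)
  set.seed(4)
  t2x <- matrix(stats::rnorm(n * n), n, n); t2x <- t2x - mean(t2x)
  u1 <- forward_displacement(d$tx, d$ty, h)
  u2 <- forward_displacement(t2x, z, h)
  u12 <- forward_displacement(d$tx + t2x, d$ty, h)
  expect_lt(max(abs(u12$ux - u1$ux - u2$ux)), 1e-10)
  ## |u| decays monotonically away from a localized patch
  mag <- sqrt(u1$ux^2 + u1$uy^2)
  prof <- vapply(seq(0, 24, by = 4), function(dy) mag[32 + dy, 32], 0)
  expect_true(all(diff(prof[3:length(prof)]) < 0))
})

test_that("regularized FTTC inverts the forward model", {
  d <- dipole_grids(n = 128, h = 0.5, width_um = 4, sep_um = 14)
  u <- forward_displacement(d$tx, d$ty, d$h)
  ## zero displacement -> zero traction
  z <- matrix(0, 128, 128)
  t0 <- reconstruct_traction(list(ux = z, uy = z), d$h, lambda = 1e-4)
  expect_true(all(t0$tx == 0))
  ## noiseless round trip (periodic inverse matching the periodic forward)
  tf <- reconstruct_traction(list(ux = u$ux, uy = u$uy), d$h, lambda = 1e-6,
                             pad = FALSE)
  rel <- sqrt(mean((tf$tx - d$tx)^2 + (tf$ty - d$ty)^2)) /
    sqrt(mean(d$tx^2 + d$ty^2))
  expect_lt(rel, 0.05)
  ## reconstructed L2 norm decreases monotonically with lambda
  rms <- vapply(10^seq(-6, 1, by = 1), function(l)
    sqrt(mean(traction_magnitude(
      reconstruct_traction(list(ux = u$ux, uy = u$uy), d$h, lambda = l,
                           pad = FALSE))^2)), 0)
  expect_true(all(diff(rms) <= 1e-9))
  ## pure drift displacement reconstructs to ~0 traction
  drift <- reconstruct_traction(list(ux = matrix(0.5, 128, 128),
                                     uy = matrix(-0.3, 128, 128)),
                                d$h, lambda = 1e-4, pad = FALSE)
  tf_mean <- mean(traction_magnitude(tf))
  expect_lt(mean(traction_magnitude(drift)), 0.01 * tf_mean)
})

test_that("bead-pair PIV displacement matches the simulator ground truth", {
  mp <- make_micropattern("disc", 40, PIXEL, c(256, 256))
  patches <- traction_dipole(c(29, 29), separation_um = 24,
                             amplitude_pa = 500, width_um = 8)
  sc <- synthetic_scene(mp, truth_traction = patches, seed = 9)
  ts <- simulate_traction_scene(sc)
  disp <- piv_displacement(ts$reference, ts$stressed, 32, 0.5)
  expect_identical(disp$units, "um")
  gx <- rep(disp$x_px, each = length(disp$y_px))
  gy <- rep(disp$y_px, times = length(disp$x_px))
  tux <- keratrack:::bilinear(ts$truth$ux, gx, gy)
  tuy <- keratrack:::bilinear(ts$truth$uy, gx, gy)
  err_px <- sqrt((as.vector(disp$u) - tux)^2 + (as.vector(disp$v) - tuy)^2) / PIXEL
  expect_lt(sqrt(mean(err_px[as.vector(disp$valid)]^2)), 0.3)
  ## stressed = reference gives a zero field
  d0 <- piv_displacement(ts$reference, ts$reference, 32, 0.5)
  expect_lt(max(abs(c(d0$u[d0$valid], d0$v[d0$valid]))), 0.01)
  ## low bead density warning
  sc_low <- sc; sc_low$beads$count <- 30L
  ts_low <- simulate_traction_scene(sc_low)
  expect_warning(piv_displacement(ts_low$reference, ts_low$stressed, 32, 0.5),
                 "bead density")
})

test_that("ROI statistics match direct oracles", {
  tx <- matrix(100, 16, 16); ty <- matrix(0, 16, 16)
  tf <- traction_field(tx, ty, 1, 11000, 0.5)
  roi <- matrix(TRUE, 16, 16)
  expect_equal(roi_traction_stats(tf, roi)$mean_pa, 100)
  ## half 0 / half 200
  tx2 <- tx; tx2[, 1:8] <- 0; tx2[, 9:16] <- 200
  tf2 <- traction_field(tx2, ty, 1, 11000, 0.5)
  expect_equal(roi_traction_stats(tf2, roi)$mean_pa, 100)
  ## random field equals the arithmetic-mean oracle
  set.seed(6)
  rx <- matrix(stats::rnorm(256), 16, 16); ry <- matrix(stats::rnorm(256), 16, 16)
  tfr <- traction_field(rx, ry, 1, 11000, 0.5)
  m <- matrix(stats::runif(256) < 0.4, 16, 16)
  st <- roi_traction_stats(tfr, m)
  expect_equal(st$mean_pa, mean(sqrt(rx[m]^2 + ry[m]^2)))
  expect_equal(st$sum_vector_pa, c(sum(rx[m]), sum(ry[m])))
  expect_equal(st$max_pa, max(sqrt(rx[m]^2 + ry[m]^2)))
  expect_error(roi_traction_stats(tfr, matrix(FALSE, 16, 16)), "empty")
})

test_that("lambda sweep tabulates the L-curve and suggests a corner", {
  d <- dipole_grids(n = 64, h = 1, width_um = 3, sep_um = 12)
  u <- forward_displacement(d$tx, d$ty, d$h)
  set.seed(2)
  un <- list(ux = u$ux + stats::rnorm(64 * 64, 0, 0.02),
             uy = u$uy + stats::rnorm(64 * 64, 0, 0.02))
  tab <- lambda_sweep(un, d$h, lambdas = 10^seq(-2, 1, by = 0.75), pad = FALSE)
  expect_identical(nrow(tab), 5L)
  ## residual grows, solution norm shrinks along the sweep
  expect_true(all(diff(tab$residual_norm) >= -1e-12))
  expect_true(all(diff(tab$solution_norm) <= 1e-12))
  expect_true(attr(tab, "suggested") %in% tab$lambda)
})
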