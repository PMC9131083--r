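## Synthetic ground-truth scenes: micropattern-confined filament networks,
## advected time series, and traction-force bead image pairs. Every generator
## is deterministic given the scene seed, so downstream estimators can be
## validated against exact ground truth.

## Run code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic scene description
#'
#' Bundles everything needed to render reproducible synthetic data: the
#' micropattern geometry, an optional ground-truth filament network, optics
#' (Gaussian PSF sigmas, background, number of z-planes), the camera noise
#' model (Poisson shot noise plus Gaussian read noise), the elastic substrate
#' (Young's modulus, Poisson ratio), fiducial-bead rendering parameters, a
#' ground-truth traction patch table, and the master seed.
#'
#' @param geometry a [make_micropattern()] object.
#' @param network optional ground-truth network from
#'   [simulate_filament_network()].
#' @param optics list: `sigma_xy_um`, `sigma_z_um`, `background`, `nz`,
#'   `z_step_um`, `amplitude` (default filament peak intensity, counts).
#' @param noise list: `poisson` (logical), `read_sigma` (counts; 0 disables).
#' @param substrate list: `E_pa` (default 11000, an 11 kPa polyacrylamide
#'   gel), `nu` (default 0.5, incompressible).
#' @param beads list: `count`, `sigma_px`, `amplitude`, `background`.
#' @param truth_traction data frame of Gaussian traction patches with columns
#'   `x_um`, `y_um`, `tx_pa`, `ty_pa`, `width_um`; see [traction_dipole()].
#' @param seed master integer seed.
#' @return an object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(geometry,
                            network = NULL,
                            optics = list(),
                            noise = list(),
                            substrate = list(),
                            beads = list(),
                            truth_traction = NULL,
                            seed = 1L) {
  stopifnot(inherits(geometry, "micropattern"))
  optics <- utils::modifyList(
    list(sigma_xy_um = 0.3, sigma_z_um = 0.6, background = 10,
         nz = 5L, z_step_um = 0.5, amplitude = 100), optics)
  noise <- utils::modifyList(list(poisson = TRUE, read_sigma = 3), noise)
  substrate <- utils::modifyList(list(E_pa = 11000, nu = 0.5), substrate)
  beads <- utils::modifyList(
    list(count = 3000L, sigma_px = 1.2, amplitude = 150, background = 5), beads)
  check_positive(optics$sigma_xy_um, "sigma_xy_um")
  check_positive(optics$sigma_z_um, "sigma_z_um")
  check_positive(substrate$E_pa, "E_pa")
  if (substrate$nu < 0 || substrate$nu > 0.5) stopf("nu must lie in [0, 0.5]")
  structure(list(geometry = geometry, network = network, optics = optics,
                 noise = noise, substrate = substrate, beads = beads,
                 truth_traction = truth_traction, cells = NULL,
                 seed = as.integer(seed)),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %s pattern, %s curves, E = %g Pa, seed %d\n",
              x$geometry$shape,
              if (is.null(x$network)) "no" else length(x$network$curves),
              x$substrate$E_pa, x$seed))
  invisible(x)
}

#' Simulate a ground-truth filament network inside a micropattern
#'
#' Draws smooth curvilinear filaments as cubic splines through 4-8 control
#' points generated by a persistent random walk: the heading turns by a
#' Gaussian increment of standard deviation `curvature_scale` (radians) at
#' each control point. Candidate curves whose sampled points leave the
#' (optionally eroded) pattern mask are re-drawn, with progressive shortening
#' so generation always terminates; every accepted sample point lies inside
#' the mask.
#'
#' @param geometry a [make_micropattern()] object with a nonempty mask.
#' @param n_curves number of filaments.
#' @param curvature_scale heading jitter per control point, radians.
#' @param length_range_um min/max target contour length, micrometers.
#' @param z_range_um axial range the filaments occupy, micrometers.
#' @param margin_um keep-out margin from the mask boundary (e.g. to leave
#'   room for later advection).
#' @param mask optional explicit logical mask overriding the pattern mask
#'   (used for per-cell territories).
#' @param n_particles number of punctate keratin particles (sub-resolution
#'   granules of the soluble/precursor pool) scattered inside the mask;
#'   default one per filament.
#' @param seed integer seed.
#' @return object of class `filament_truth`: list with `curves` (list of
#'   `n x 3` matrices in micrometers, sampled at quarter-pixel arc spacing),
#'   `profiles` (per-curve smooth intensity modulation along the arc),
#'   `amplitude` (per-curve relative intensity), `particles` (`n x 3` matrix,
#'   um), and `seed`.
#' @export
simulate_filament_network <- function(geometry, n_curves = 40,
                                      curvature_scale = 0.35,
                                      length_range_um = c(6, 20),
                                      z_range_um = c(0.4, 1.6),
                                      margin_um = 0.5,
                                      mask = NULL,
                                      n_particles = n_curves,
                                      seed = 1L) {
  stopifnot(inherits(geometry, "micropattern"))
  if (n_curves < 0) stopf("n_curves must be >= 0")
  psz <- geometry$pixel_size_um
  m <- mask %||% geometry$mask
  if (margin_um > 0) m <- erode_mask(m, margin_um / psz)
  if (!any(m)) stopf("empty (or fully eroded) pattern mask")
  idx <- which(m, arr.ind = TRUE)  # [y, x] 1-based
  ds_um <- 0.25 * psz

  inside <- function(P_um) {
    xp <- round(P_um[, 1] / psz) + 1L
    yp <- round(P_um[, 2] / psz) + 1L
    ok <- xp >= 1 & xp <= ncol(m) & yp >= 1 & yp <= nrow(m)
    all(ok) && all(m[cbind(yp, xp)])
  }

  draw_curve <- function() {
    L <- stats::runif(1, length_range_um[1], length_range_um[2])
    for (attempt in seq_len(80)) {
      if (attempt %% 20 == 0) L <- 0.7 * L
      n_ctrl <- sample(4:8, 1)
      start <- idx[sample(nrow(idx), 1), ]
      p <- c((start[2] - 1 + stats::runif(1, -0.5, 0.5)) * psz,
             (start[1] - 1 + stats::runif(1, -0.5, 0.5)) * psz)
      theta <- stats::runif(1, 0, 2 * pi)
      step <- L / (n_ctrl - 1)
      ctrl <- matrix(NA_real_, n_ctrl, 3)
      z <- stats::runif(1, z_range_um[1], z_range_um[2])
      ctrl[1, ] <- c(p, z)
      ok <- TRUE
      for (i in 2:n_ctrl) {
        theta <- theta + stats::rnorm(1, 0, curvature_scale)
        p <- p + step * c(cos(theta), sin(theta))
        z <- min(max(z + stats::rnorm(1, 0, 0.1), z_range_um[1]), z_range_um[2])
        ctrl[i, ] <- c(p, z)
      }
      ## cubic spline through control points, chord-length parameterized
      tpar <- c(0, cumsum(sqrt(rowSums(diff(ctrl)^2))))
      if (any(diff(tpar) <= 0)) next
      tfine <- seq(0, tpar[n_ctrl], length.out = max(20, ceiling(tpar[n_ctrl] / (ds_um / 2))))
      fine <- vapply(1:3, function(j) stats::spline(tpar, ctrl[, j], xout = tfine)$y,
                     numeric(length(tfine)))
      P <- resample_polyline(fine, ds_um)
      if (nrow(P) >= 5 && inside(P)) return(P)
    }
    NULL
  }

  with_seed(seed, {
    curves <- list()
    profiles <- list()
    if (n_curves > 0) {
      for (k in seq_len(n_curves)) {
        cv <- draw_curve()
        if (is.null(cv)) stopf("could not place curve %d inside the mask", k)
        curves[[k]] <- cv
        ## smooth intensity modulation along the bundle (+-30%)
        nsamp <- nrow(cv)
        raw <- stats::rnorm(nsamp)
        kern <- gauss_kernel(max(2, nsamp / 10))
        sm <- sep_filter(matrix(raw, ncol = 1), kern, 1)[, 1]
        sdv <- stats::sd(sm)
        profiles[[k]] <- 1 + 0.3 * (if (sdv > 0) sm / sdv else sm * 0)
      }
    }
    amplitude <- if (n_curves > 0) stats::runif(n_curves, 0.7, 1.3) else numeric(0)
    particles <- if (n_particles > 0) {
      pi_idx <- idx[sample(nrow(idx), n_particles, replace = TRUE), , drop = FALSE]
      cbind((pi_idx[, 2] - 1 + stats::runif(n_particles, -0.5, 0.5)) * psz,
            (pi_idx[, 1] - 1 + stats::runif(n_particles, -0.5, 0.5)) * psz,
            stats::runif(n_particles, z_range_um[1], z_range_um[2]))
    } else matrix(numeric(0), 0, 3)
    structure(list(curves = curves, profiles = profiles, amplitude = amplitude,
                   particles = particles, seed = as.integer(seed)),
              class = "filament_truth")
  })
}

## Deposit polyline samples into a (nz, ny, nx) array with trilinear weights.
## `weights` is a list of per-sample deposit vectors (recycled if scalar).
splat_curves <- function(curves, weights, nz, ny, nx, psz, z_step) {
  acc <- numeric(nz * ny * nx)
  for (k in seq_along(curves)) {
    P <- curves[[k]]
    x <- P[, 1] / psz; y <- P[, 2] / psz
    z <- pmin(pmax(P[, 3] / z_step, 0), nz - 1)
    w0 <- rep_len(weights[[k]], nrow(P))
    x0 <- pmin(pmax(floor(x), 0), nx - 2); fx <- x - x0
    y0 <- pmin(pmax(floor(y), 0), ny - 2); fy <- y - y0
    z0 <- pmin(pmax(floor(z), 0), max(nz - 2, 0)); fz <- if (nz > 1) z - z0 else 0
    for (dz in 0:(if (nz > 1) 1 else 0)) for (dy in 0:1) for (dx in 0:1) {
      w <- w0 * (if (dz) fz else 1 - fz) * (if (dy) fy else 1 - fy) *
        (if (dx) fx else 1 - fx)
      lin <- (z0 + dz) + nz * (y0 + dy) + nz * ny * (x0 + dx) + 1
      agg <- rowsum(w, lin)
      ii <- as.integer(rownames(agg))
      acc[ii] <- acc[ii] + agg[, 1]
    }
  }
  array(acc, c(nz, ny, nx))
}

## PSF blur + noise applied to a raw deposition array; shared by all renderers.
render_raw <- function(dep, optics, noise, psz, add_noise = TRUE) {
  nz <- dim(dep)[1]; ny <- dim(dep)[2]; nx <- dim(dep)[3]
  s_xy <- optics$sigma_xy_um / psz
  for (z in seq_len(nz)) dep[z, , ] <- gauss_blur2d(dep[z, , ], s_xy)
  if (nz > 1) {
    s_z <- optics$sigma_z_um / optics$z_step_um
    kz <- gauss_kernel(s_z)
    flat <- matrix(dep, nz, ny * nx)
    flat <- sep_filter(flat, kz, 1)
    dep <- array(flat, c(nz, ny, nx))
  }
  img <- dep + optics$background
  if (add_noise) {
    ## inverse-CDF Poisson: exactly one uniform per voxel, so voxels whose
    ## expected signal is unchanged (e.g. cells untouched by an ablation)
    ## receive bit-identical noise under the same seed
    if (isTRUE(noise$poisson))
      img[] <- stats::qpois(stats::runif(length(img)), pmax(img, 0))
    if (noise$read_sigma > 0) img <- img + stats::rnorm(length(img), 0, noise$read_sigma)
  }
  img[img < 0] <- 0
  img
}

## Per-sample deposit weight so a filament's in-focus ridge peak is close to
## `amplitude` counts after PSF blurring.
deposit_weight <- function(amplitude, optics, psz, ds_um) {
  s_xy <- optics$sigma_xy_um / psz
  zk <- if (optics$nz > 1) max(gauss_kernel(optics$sigma_z_um / optics$z_step_um)) else 1
  amplitude * (ds_um / psz) * s_xy * sqrt(2 * pi) / zk
}

## Deposit weight for a sub-resolution particle to reach ~`amplitude` at peak.
particle_weight <- function(amplitude, optics, psz) {
  s_xy <- optics$sigma_xy_um / psz
  zk <- if (optics$nz > 1) max(gauss_kernel(optics$sigma_z_um / optics$z_step_um)) else 1
  amplitude * 2 * pi * s_xy^2 / zk
}

## Assemble the full deposit for a truth network: filament samples with their
## intensity profiles plus punctate particles.
network_deposit <- function(net, optics, psz, ds_um, nz, ny, nx) {
  wf <- deposit_weight(optics$amplitude * net$amplitude, optics, psz, ds_um)
  wlist <- lapply(seq_along(net$curves), function(k)
    wf[k] * (net$profiles[[k]] %||% 1))
  pieces <- net$curves
  if (!is.null(net$particles) && nrow(net$particles) > 0) {
    pieces <- c(pieces, list(net$particles))
    wlist <- c(wlist, list(rep(particle_weight(optics$amplitude, optics, psz),
                               nrow(net$particles))))
  }
  splat_curves(pieces, wlist, nz, ny, nx, psz, optics$z_step_um)
}

#' Render a filament network as a fluorescence z-stack
#'
#' Curves are deposited into the voxel grid with trilinear weights at
#' quarter-pixel arc spacing, blurred with a separable Gaussian PSF
#' (`sigma_xy_um` laterally, `sigma_z_um` axially), offset by the background
#' level, and optionally degraded with Poisson shot noise plus Gaussian read
#' noise (clamped at zero). With noise disabled, intensity ridges coincide
#' with the ground-truth centerlines to within a voxel.
#'
#' @param scene a [synthetic_scene()] whose `network` is set (or pass one).
#' @param network optional override of `scene$network`.
#' @param add_noise apply the scene's noise model (default: scene setting).
#' @return an [image_stack] of dimension `(nz, ny, nx)`.
#' @export
render_network_stack <- function(scene, network = NULL, add_noise = TRUE) {
  stopifnot(inherits(scene, "synthetic_scene"))
  net <- network %||% scene$network
  if (is.null(net)) stopf("scene has no network to render")
  g <- scene$geometry
  ny <- g$image_shape[1]; nx <- g$image_shape[2]
  nz <- scene$optics$nz
  psz <- g$pixel_size_um
  ds_um <- 0.25 * psz
  dep <- network_deposit(net, scene$optics, psz, ds_um, nz, ny, nx)
  img <- with_seed(scene$seed + 1L,
                   render_raw(dep, scene$optics, scene$noise, psz, add_noise))
  image_stack(img, psz, scene$optics$z_step_um, channel = "keratin")
}

#' Simulate an advected time-lapse of the filament network
#'
#' Produces a rendered time series plus the exact per-frame ground truth.
#' Three motion modes are supported: `uniform` translation at
#' `flow_speed_um_per_min` along `direction_deg`; `radial` inward flow whose
#' speed grows linearly with distance from the pattern center (peripheral
#' flow is fastest, as in confined keratinocytes); and `rotation`, rigid
#' rotation at `omega_deg_per_frame` about the pattern center. Points whose
#' advected position would leave the pattern mask stop moving and the
#' returned metadata carries a `clipped` flag.
#'
#' @param scene a [synthetic_scene()] with a network.
#' @param flow_speed_um_per_min flow speed (uniform: everywhere; radial:
#'   at the pattern edge).
#' @param n_frames number of frames (>= 2).
#' @param dt_min frame interval, minutes.
#' @param mode `"uniform"`, `"radial"` or `"rotation"`.
#' @param direction_deg flow direction for `uniform` mode.
#' @param omega_deg_per_frame rigid rotation per frame (`rotation` mode);
#'   positive is anticlockwise in Cartesian (y-up) convention.
#' @param add_noise render with the scene noise model.
#' @return list of class `flow_series`: `stack` (4D [image_stack]),
#'   `truth` (per-frame data frame), `clipped` flag.
#' @export
simulate_flow_series <- function(scene, flow_speed_um_per_min = 0.3,
                                 n_frames = 5, dt_min = 1,
                                 mode = c("uniform", "radial", "rotation"),
                                 direction_deg = 0,
                                 omega_deg_per_frame = 2,
                                 add_noise = TRUE) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (n_frames < 2) stopf("n_frames must be >= 2")
  mode <- match.arg(mode)
  g <- scene$geometry
  psz <- g$pixel_size_um
  ny <- g$image_shape[1]; nx <- g$image_shape[2]
  nz <- scene$optics$nz
  ds_um <- 0.25 * psz
  center_um <- g$center_px * psz
  R_um <- if (is.finite(g$diameter_um)) g$diameter_um / 2 else
    min(ny, nx) * psz / 2
  m <- g$mask
  inside_mask <- function(x_um, y_um) {
    xp <- round(x_um / psz) + 1L; yp <- round(y_um / psz) + 1L
    ok <- xp >= 1 & xp <= ncol(m) & yp >= 1 & yp <= nrow(m)
    ok[ok] <- m[cbind(yp[ok], xp[ok])]
    ok
  }
  advect <- function(P) {
    x <- P[, 1]; y <- P[, 2]
    d <- switch(mode,
      uniform = {
        a <- direction_deg * pi / 180
        v <- flow_speed_um_per_min * dt_min
        cbind(rep(v * cos(a), length(x)), rep(v * sin(a), length(x)))
      },
      radial = {
        rx <- x - center_um[1]; ry <- y - center_um[2]
        r <- pmax(sqrt(rx^2 + ry^2), 1e-9)
        sp <- flow_speed_um_per_min * (r / R_um) * dt_min
        cbind(-sp * rx / r, -sp * ry / r)
      },
      rotation = {
        ## positive omega = anticlockwise with y up; image y points down,
        ## so the pixel-space rotation matrix has the opposite sense
        a <- -omega_deg_per_frame * pi / 180
        rx <- x - center_um[1]; ry <- y - center_um[2]
        cbind(rx * cos(a) - ry * sin(a) - rx, rx * sin(a) + ry * cos(a) - ry)
      })
    newx <- x + d[, 1]; newy <- y + d[, 2]
    ok <- inside_mask(newx, newy)
    P2 <- P
    P2[ok, 1] <- newx[ok]; P2[ok, 2] <- newy[ok]
    attr(P2, "clipped") <- any(!ok)
    P2
  }
  net <- scene$network
  if (is.null(net)) stopf("scene has no network")
  frames <- vector("list", n_frames)
  cur <- net
  clipped <- FALSE
  with_seed(scene$seed + 2L, {
    for (k in seq_len(n_frames)) {
      if (k > 1) {
        cur$curves <- lapply(cur$curves, advect)
        if (nrow(cur$particles %||% matrix(0, 0, 3)) > 0)
          cur$particles <- advect(cur$particles)
        clipped <- clipped ||
          any(vapply(cur$curves, function(p) isTRUE(attr(p, "clipped")), logical(1))) ||
          isTRUE(attr(cur$particles, "clipped"))
      }
      dep <- network_deposit(cur, scene$optics, psz, ds_um, nz, ny, nx)
      frames[[k]] <- render_raw(dep, scene$optics, scene$noise, psz, add_noise)
    }
  })
  if (clipped)
    warning("some curve points reached the mask boundary and were frozen",
            call. = FALSE)
  arr <- array(0, c(n_frames, nz, ny, nx))
  for (k in seq_len(n_frames)) arr[k, , , ] <- frames[[k]]
  truth <- data.frame(
    frame = seq_len(n_frames) - 1L,
    dx_um = if (mode == "uniform")
      (seq_len(n_frames) - 1L) * flow_speed_um_per_min * dt_min *
        cos(direction_deg * pi / 180) else NA_real_,
    dy_um = if (mode == "uniform")
      (seq_len(n_frames) - 1L) * flow_speed_um_per_min * dt_min *
        sin(direction_deg * pi / 180) else NA_real_,
    speed_um_min = if (mode == "uniform") flow_speed_um_per_min else NA_real_,
    omega_deg_per_frame = if (mode == "rotation") omega_deg_per_frame else NA_real_)
  structure(list(
    stack = image_stack(arr, psz, scene$optics$z_step_um, dt_min, "keratin"),
    truth = truth, mode = mode, clipped = clipped), class = "flow_series")
}

#' Gaussian traction dipole patch table
#'
#' Convenience constructor for a force-balanced pair of Gaussian traction
#' patches: two patches of width `width_um` separated by `separation_um`
#' along `axis_deg`, carrying equal and opposite traction of magnitude
#' `amplitude_pa` along the same axis (pointing inwards = contractile).
#'
#' @param center_um dipole midpoint `c(x, y)` in micrometers.
#' @param axis_deg dipole axis, degrees.
#' @param separation_um patch center separation, micrometers.
#' @param amplitude_pa traction magnitude per patch, Pa.
#' @param width_um Gaussian patch sigma, micrometers.
#' @return data frame with one row per patch
#'   (`x_um, y_um, tx_pa, ty_pa, width_um`).
#' @export
traction_dipole <- function(center_um, axis_deg = 0, separation_um = 10,
                            amplitude_pa = 500, width_um = 2) {
  a <- axis_deg * pi / 180
  u <- c(cos(a), sin(a))
  h <- separation_um / 2
  data.frame(
    x_um = center_um[1] + c(h, -h) * u[1],
    y_um = center_um[2] + c(h, -h) * u[2],
    tx_pa = c(-amplitude_pa, amplitude_pa) * u[1],
    ty_pa = c(-amplitude_pa, amplitude_pa) * u[2],
    width_um = width_um)
}

## Evaluate traction patch table on the pixel grid -> list(tx, ty) in Pa.
traction_patch_grids <- function(patches, ny, nx, psz) {
  X <- matrix(rep(seq_len(nx) - 1, each = ny), ny, nx) * psz
  Y <- matrix(rep(seq_len(ny) - 1, nx), ny, nx) * psz
  tx <- matrix(0, ny, nx); ty <- matrix(0, ny, nx)
  for (i in seq_len(nrow(patches))) {
    gsh <- exp(-((X - patches$x_um[i])^2 + (Y - patches$y_um[i])^2) /
                 (2 * patches$width_um[i]^2))
    tx <- tx + patches$tx_pa[i] * gsh
    ty <- ty + patches$ty_pa[i] * gsh
  }
  list(tx = tx, ty = ty)
}

#' Simulate a traction-force bead image pair
#'
#' Builds the ground-truth traction field from the scene's Gaussian patch
#' table, solves the forward Boussinesq problem on the pixel grid
#' ([forward_displacement()]), seeds fiducial beads uniformly at random, and
#' renders a relaxed (reference) and a deformed (stressed) bead image, where
#' each bead moves by the forward displacement interpolated at its position.
#' The traction field must be force-balanced.
#'
#' @param scene a [synthetic_scene()] with `truth_traction` patches set.
#' @param add_noise render with the scene noise model.
#' @return list of class `traction_scene`: `reference`/`stressed`
#'   ([image_stack], single plane), `beads` (data frame with positions in px
#'   and true displacements in um), `truth` (list: `tx`, `ty` Pa pixel grids,
#'   `ux`, `uy` um displacement grids, patch table), and the scene.
#' @export
simulate_traction_scene <- function(scene, add_noise = TRUE) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (is.null(scene$truth_traction)) stopf("scene has no truth_traction patches")
  g <- scene$geometry
  ny <- g$image_shape[1]; nx <- g$image_shape[2]
  psz <- g$pixel_size_um
  tg <- traction_patch_grids(scene$truth_traction, ny, nx, psz)
  tot <- sum(sqrt(tg$tx^2 + tg$ty^2))
  if (tot > 0) {
    relx <- abs(sum(tg$tx)) / tot; rely <- abs(sum(tg$ty)) / tot
    if (relx > 0.05 || rely > 0.05)
      stopf("truth traction is not force-balanced (net force %.3g, %.3g relative)",
            sum(tg$tx) / tot, sum(tg$ty) / tot)
    ## remove the residual net force from truncating Gaussian tails at the
    ## frame edge, so the discrete field is balanced to machine precision
    tg$tx <- tg$tx - mean(tg$tx)
    tg$ty <- tg$ty - mean(tg$ty)
  }
  disp <- forward_displacement(tg$tx, tg$ty, grid_spacing_um = psz,
                               E_pa = scene$substrate$E_pa,
                               nu = scene$substrate$nu)
  nb <- scene$beads$count
  if (nb <= 0) stopf("bead_count must be positive")
  with_seed(scene$seed + 3L, {
    bx <- stats::runif(nb, 2, nx - 3)
    by <- stats::runif(nb, 2, ny - 3)
    bamp <- stats::runif(nb, 0.7, 1.3) * scene$beads$amplitude
    ux <- bilinear(disp$ux, bx, by)   # um
    uy <- bilinear(disp$uy, bx, by)
    ref <- render_beads(bx, by, bamp, ny, nx, scene$beads$sigma_px)
    str <- render_beads(bx + ux / psz, by + uy / psz, bamp, ny, nx,
                        scene$beads$sigma_px)
    noisify <- function(img) {
      img <- img + scene$beads$background
      if (add_noise) {
        if (isTRUE(scene$noise$poisson))
          img[] <- stats::qpois(stats::runif(length(img)), pmax(img, 0))
        if (scene$noise$read_sigma > 0)
          img <- img + stats::rnorm(length(img), 0, scene$noise$read_sigma)
      }
      img[img < 0] <- 0
      img
    }
    ref <- noisify(ref); str <- noisify(str)
    structure(list(
      reference = image_stack(ref, psz, channel = "beads"),
      stressed = image_stack(str, psz, channel = "beads"),
      beads = data.frame(x_px = bx, y_px = by, ux_um = ux, uy_um = uy),
      truth = list(tx = tg$tx, ty = tg$ty, ux = disp$ux, uy = disp$uy,
                   patches = scene$truth_traction),
      scene = scene), class = "traction_scene")
  })
}

## Analytic Gaussian spot rendering (vectorized over beads via local windows).
render_beads <- function(x, y, amp, ny, nx, sigma_px) {
  img <- matrix(0, ny, nx)
  r <- ceiling(4 * sigma_px)
  for (i in seq_along(x)) {
    x0 <- max(0, floor(x[i]) - r); x1 <- min(nx - 1, floor(x[i]) + r + 1)
    y0 <- max(0, floor(y[i]) - r); y1 <- min(ny - 1, floor(y[i]) + r + 1)
    if (x1 < x0 || y1 < y0) next
    gx <- exp(-((x0:x1) - x[i])^2 / (2 * sigma_px^2))
    gy <- exp(-((y0:y1) - y[i])^2 / (2 * sigma_px^2))
    img[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] <-
      img[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] + amp[i] * outer(gy, gx)
  }
  img
}

#' Simulate a confined cell group with per-cell territories
#'
#' Partitions the micropattern into `n_cells` Voronoi territories around
#' evenly spaced seed points, grows an independent filament network inside
#' each territory, and assigns each cell a contractile traction dipole
#' pointing along the line through the pattern center. Used for the per-cell
#' analyses and the photoablation scenario.
#'
#' @param geometry a [make_micropattern()] object.
#' @param n_cells number of cells.
#' @param curves_per_cell filaments per cell.
#' @param amplitude_pa traction dipole magnitude per cell, Pa.
#' @param patch_width_um traction patch sigma, micrometers.
#' @param seed integer seed.
#' @param ... further arguments to [synthetic_scene()].
#' @return a [synthetic_scene()] with `cells` set: per-cell masks, curve
#'   indices, and traction patch row indices.
#' @export
simulate_cell_group <- function(geometry, n_cells = 4, curves_per_cell = 10,
                                amplitude_pa = 600, patch_width_um = 2.5,
                                seed = 1L, ...) {
  stopifnot(inherits(geometry, "micropattern"))
  g <- geometry
  psz <- g$pixel_size_um
  ny <- g$image_shape[1]; nx <- g$image_shape[2]
  R_um <- g$diameter_um / 2
  c_um <- g$center_px * psz
  ang <- 2 * pi * (seq_len(n_cells) - 1) / n_cells + pi / n_cells
  seeds <- cbind(c_um[1] + 0.5 * R_um * cos(ang),
                 c_um[2] + 0.5 * R_um * sin(ang))
  X <- matrix(rep(seq_len(nx) - 1, each = ny), ny, nx) * psz
  Y <- matrix(rep(seq_len(ny) - 1, nx), ny, nx) * psz
  d2 <- lapply(seq_len(n_cells),
               function(i) (X - seeds[i, 1])^2 + (Y - seeds[i, 2])^2)
  ## nearest-seed labeling
  darr <- array(unlist(d2), c(ny, nx, n_cells))
  lab <- apply(darr, c(1, 2), which.min)
  lab[!g$mask] <- 0L
  masks <- lapply(seq_len(n_cells), function(i) lab == i)

  nets <- vector("list", n_cells)
  patches <- NULL
  patch_index <- vector("list", n_cells)
  curve_index <- vector("list", n_cells)
  curves <- list(); amps <- numeric(0)
  for (i in seq_len(n_cells)) {
    nets[[i]] <- simulate_filament_network(
      g, n_curves = curves_per_cell, mask = masks[[i]],
      length_range_um = c(4, 12), margin_um = 0.4,
      seed = seed + 100L * i)
    curve_index[[i]] <- length(curves) + seq_along(nets[[i]]$curves)
    curves <- c(curves, nets[[i]]$curves)
    amps <- c(amps, nets[[i]]$amplitude)
    dip <- traction_dipole(seeds[i, ], axis_deg = ang[i] * 180 / pi,
                           separation_um = 0.6 * R_um,
                           amplitude_pa = amplitude_pa,
                           width_um = patch_width_um)
    patch_index[[i]] <- (if (is.null(patches)) 0 else nrow(patches)) + 1:2
    patches <- rbind(patches, dip)
  }
  net <- structure(list(curves = curves, amplitude = amps, seed = as.integer(seed)),
                   class = "filament_truth")
  scene <- synthetic_scene(g, network = net, truth_traction = patches,
                           seed = seed, ...)
  scene$cells <- list(masks = masks, curve_index = curve_index,
                      patch_index = patch_index, seeds_um = seeds)
  scene
}

#' Photoablation scenario: remove one cell, scale all tractions
#'
#' Emulates photo-oxidation of a single cell within a confined group: the
#' ablated cell's filaments are removed from the ground-truth network and
#' every traction patch amplitude is multiplied by `traction_scale`
#' (mimicking the overall traction reduction observed after ablation). Other
#' cells' filaments are untouched.
#'
#' @param scene a [simulate_cell_group()] scene.
#' @param ablated_cell_index which cell to ablate (1-based); `0` ablates none.
#' @param traction_scale multiplier in (0, 1] applied to all patch amplitudes.
#' @return a new `synthetic_scene` (same class/seed) with the modification
#'   applied; `$ablation` records what was done.
#' @export
simulate_ablation <- function(scene, ablated_cell_index, traction_scale = 0.8) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (is.null(scene$cells)) stopf("scene has no cell partition; use simulate_cell_group()")
  if (traction_scale <= 0 || traction_scale > 1)
    stopf("traction_scale must lie in (0, 1]")
  n_cells <- length(scene$cells$masks)
  if (!ablated_cell_index %in% 0:n_cells)
    stopf("ablated_cell_index must be in 0..%d", n_cells)
  out <- scene
  if (ablated_cell_index > 0) {
    drop <- scene$cells$curve_index[[ablated_cell_index]]
    keep <- setdiff(seq_along(scene$network$curves), drop)
    out$network$curves <- scene$network$curves[keep]
    out$network$amplitude <- scene$network$amplitude[keep]
    ## remap per-cell curve indices
    remap <- match(seq_along(scene$network$curves), keep)
    out$cells$curve_index <- lapply(seq_len(n_cells), function(i) {
      if (i == ablated_cell_index) integer(0)
      else remap[scene$cells$curve_index[[i]]]
    })
  }
  out$truth_traction$tx_pa <- scene$truth_traction$tx_pa * traction_scale
  out$truth_traction$ty_pa <- scene$truth_traction$ty_pa * traction_scale
  out$ablation <- list(cell = ablated_cell_index, traction_scale = traction_scale)
  out
}
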