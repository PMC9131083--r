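#' Boussinesq Green's tensor in Fourier space
#'
#' Fourier-space solution of the elastic half-space (Boussinesq) problem
#' relating in-plane surface traction to in-plane surface displacement,
#' evaluated at a single wavevector:
#' \deqn{\hat G(k) = \frac{2(1+\nu)}{E k^3}
#'   \begin{pmatrix}(1-\nu)k^2+\nu k_y^2 & -\nu k_x k_y\\
#'                  -\nu k_x k_y & (1-\nu)k^2+\nu k_x^2\end{pmatrix}}
#' with \eqn{k = \sqrt{k_x^2+k_y^2}}. Wavevectors are in rad/um and `E_pa`
#' in Pa, so the tensor has units um/Pa.
#'
#' @param kx,ky wavevector components, rad/um (not both zero).
#' @param E_pa substrate Young's modulus, Pa.
#' @param nu substrate Poisson ratio in [0, 0.5].
#' @return symmetric 2x2 matrix.
#' @export
greens_tensor <- function(kx, ky, E_pa = 11000, nu = 0.5) {
  if (kx == 0 && ky == 0) stopf("Green's tensor is undefined at k = 0")
  if (nu < 0 || nu > 0.5) stopf("nu must lie in [0, 0.5]")
  check_positive(E_pa, "E_pa")
  k2 <- kx^2 + ky^2
  k <- sqrt(k2)
  pref <- 2 * (1 + nu) / (E_pa * k^3)
  matrix(pref * c((1 - nu) * k2 + nu * ky^2, -nu * kx * ky,
                  -nu * kx * ky, (1 - nu) * k2 + nu * kx^2), 2, 2)
}

## Grid-wise Green's tensor components for an ny x nx grid with spacing h um.
## Returns list(G11, G12, G22, k) with the zero mode set to 0.
greens_grids <- function(ny, nx, h, E_pa, nu) {
  kx <- 2 * pi * fft_freq(nx) / h
  ky <- 2 * pi * fft_freq(ny) / h
  KX <- matrix(rep(kx, each = ny), ny, nx)
  KY <- matrix(rep(ky, times = nx), ny, nx)
  K2 <- KX^2 + KY^2
  K <- sqrt(K2)
  K[1, 1] <- Inf  # kill the zero mode
  pref <- 2 * (1 + nu) / (E_pa * K^3)
  list(G11 = pref * ((1 - nu) * K2 + nu * KY^2),
       G12 = -pref * nu * KX * KY,
       G22 = pref * ((1 - nu) * K2 + nu * KX^2),
       K = K)
}

#' Forward elastic solution: traction to surface displacement
#'
#' Applies the Boussinesq Green's tensor mode by mode on a periodic grid:
#' \eqn{\hat u(k) = \hat G(k)\,\hat t(k)}, with the zero mode set to zero
#' (force balance). Used to generate ground-truth bead displacements and as
#' the forward operator in round-trip validation of the traction
#' reconstruction.
#'
#' @param tx,ty traction components in Pa, equal-size matrices on a uniform
#'   square-spaced grid.
#' @param grid_spacing_um grid spacing, micrometers.
#' @param E_pa,nu substrate elastic parameters.
#' @return list with displacement grids `ux`, `uy` in micrometers.
#' @export
forward_displacement <- function(tx, ty, grid_spacing_um, E_pa = 11000, nu = 0.5) {
  if (!all(dim(tx) == dim(ty))) stopf("tx and ty must have equal shapes")
  check_positive(grid_spacing_um, "grid_spacing_um")
  ny <- nrow(tx); nx <- ncol(tx)
  G <- greens_grids(ny, nx, grid_spacing_um, E_pa, nu)
  Tx <- stats::fft(tx); Ty <- stats::fft(ty)
  Ux <- G$G11 * Tx + G$G12 * Ty
  Uy <- G$G12 * Tx + G$G22 * Ty
  Ux[1, 1] <- 0; Uy[1, 1] <- 0
  list(ux = Re(stats::fft(Ux, inverse = TRUE)) / (ny * nx),
       uy = Re(stats::fft(Uy, inverse = TRUE)) / (ny * nx))
}

#' Traction field container
#'
#' Grid of reconstructed (or ground-truth) traction vectors in Pa together
#' with the elastic and regularization parameters that produced it.
#'
#' @param tx,ty traction components, Pa, matrices `[y, x]`.
#' @param grid_spacing_um grid spacing, micrometers.
#' @param E_pa,nu,lambda elastic modulus, Poisson ratio, regularization.
#' @param x_px,y_px optional grid coordinates in image pixels.
#' @return object of class `traction_field`.
#' @export
traction_field <- function(tx, ty, grid_spacing_um, E_pa, nu, lambda = NA,
                           x_px = NULL, y_px = NULL) {
  stopifnot(all(dim(tx) == dim(ty)))
  if (anyNA(tx) || anyNA(ty) || any(!is.finite(tx)) || any(!is.finite(ty)))
    stopf("traction values must be finite")
  structure(list(tx = tx, ty = ty, grid_spacing_um = grid_spacing_um,
                 E_pa = E_pa, nu = nu, lambda = lambda,
                 x_px = x_px %||% (seq_len(ncol(tx)) - 1),
                 y_px = y_px %||% (seq_len(nrow(tx)) - 1)),
            class = "traction_field")
}

#' @export
print.traction_field <- function(x, ...) {
  mag <- sqrt(x$tx^2 + x$ty^2)
  cat(sprintf("<traction_field> %d x %d, E = %g Pa, nu = %.2f, lambda = %g, mean |t| = %.1f Pa\n",
              nrow(x$tx), ncol(x$tx), x$E_pa, x$nu, x$lambda, mean(mag)))
  invisible(x)
}

#' Traction magnitude map
#' @param tf a [traction_field()].
#' @return matrix of per-node Euclidean norms, Pa.
#' @export
traction_magnitude <- function(tf) sqrt(tf$tx^2 + tf$ty^2)

#' Bead displacement by PIV
#'
#' Windowed normalized cross-correlation between the drift-aligned reference
#' (relaxed) and stressed bead images, returning displacements in
#' micrometers. Identical correlation engine as the keratin flow analysis,
#' without the division by the frame interval. A warning flag is set when
#' the estimated bead density falls below ~3 beads per window.
#'
#' @param reference,stressed equal-size matrices or single-plane
#'   [image_stack]s (already drift-aligned, see [align_drift()]).
#' @param window_px,overlap interrogation window size (px) and overlap.
#' @param pixel_size_um lateral pixel size (taken from the stack if given).
#' @param mask optional logical matrix restricting analysis.
#' @return a [vector_field()] in micrometers with attribute `low_density`.
#' @export
piv_displacement <- function(reference, stressed, window_px = 32L,
                             overlap = 0.5, pixel_size_um = NULL,
                             mask = NULL) {
  if (inherits(reference, "image_stack")) {
    pixel_size_um <- pixel_size_um %||% reference$pixel_size_um
    reference <- stack_plane(reference)
  }
  if (inherits(stressed, "image_stack")) stressed <- stack_plane(stressed)
  pixel_size_um <- pixel_size_um %||% 0.23
  vf <- piv_core(reference, stressed, window_px, overlap, mask)
  ## crude bead density check: count distinct local maxima well above
  ## background (a quarter of the dynamic range over the median)
  med <- stats::median(reference)
  bgcut <- med + 0.25 * (max(reference) - med)
  locmax <- reference > bgcut &
    reference >= shift_mat(reference, 1, 0, Inf) &
    reference >= shift_mat(reference, -1, 0, Inf) &
    reference >= shift_mat(reference, 0, 1, Inf) &
    reference >= shift_mat(reference, 0, -1, Inf)
  per_window <- sum(locmax) * window_px^2 / length(reference)
  low <- per_window < 3
  if (low)
    warning(sprintf("low bead density (~%.1f beads/window); PIV may be unreliable",
                    per_window), call. = FALSE)
  vf$u <- vf$u * pixel_size_um
  vf$v <- vf$v * pixel_size_um
  vf$units <- "um"
  vf$pixel_size_um <- pixel_size_um
  attr(vf, "low_density") <- low
  vf
}

#' Regularized Fourier-transform traction cytometry (FTTC)
#'
#' Inverts the Boussinesq relation mode by mode with zeroth-order Tikhonov
#' regularization: \eqn{\hat t = (\hat G^T\hat G + \lambda^2 s I)^{-1}
#' \hat G^T \hat u}, where `s` is the mean diagonal of
#' \eqn{\hat G^T \hat G} over all nonzero modes, making `lambda`
#' dimensionless. Invalid PIV vectors are interpolated first (the filled
#' fraction is reported); the displacement grid is zero-padded to twice its
#' size before the FFT to suppress periodic-boundary artifacts and cropped
#' after inversion (`pad = FALSE` gives the plain periodic inverse, the exact
#' adjoint of [forward_displacement()]).
#'
#' @param displacement a [vector_field()] in micrometers (from
#'   [piv_displacement()]), or a list with matrices `ux`, `uy` in um.
#' @param grid_spacing_um spacing of the displacement grid, micrometers
#'   (inferred from a PIV field as window step times pixel size).
#' @param E_pa,nu substrate elastic parameters (defaults: 11 kPa gel,
#'   incompressible).
#' @param lambda dimensionless regularization parameter (>= 0).
#' @param pad zero-pad to 2x before the FFT (default TRUE).
#' @return a [traction_field()]; attribute `fraction_filled` reports the
#'   share of interpolated grid nodes.
#' @export
reconstruct_traction <- function(displacement, grid_spacing_um = NULL,
                                 E_pa = 11000, nu = 0.5, lambda = 1e-4,
                                 pad = TRUE) {
  if (lambda < 0) stopf("lambda must be >= 0")
  frac <- 0
  x_px <- NULL; y_px <- NULL
  if (inherits(displacement, "vector_field")) {
    if (!identical(displacement$units, "um"))
      stopf("displacement field must be in micrometers")
    filled <- fill_invalid_field(displacement)
    ux <- filled$u; uy <- filled$v
    frac <- filled$fraction_filled
    x_px <- displacement$x_px; y_px <- displacement$y_px
    if (is.null(grid_spacing_um)) {
      step_px <- diff(displacement$x_px[1:2])
      grid_spacing_um <- step_px * displacement$pixel_size_um
    }
  } else {
    ux <- displacement$ux; uy <- displacement$uy
    if (is.null(grid_spacing_um)) stopf("grid_spacing_um required for raw grids")
  }
  check_positive(grid_spacing_um, "grid_spacing_um")
  ny <- nrow(ux); nx <- ncol(ux)
  if (pad) {
    NY <- 2L * ny; NX <- 2L * nx
    UX <- matrix(0, NY, NX); UY <- matrix(0, NY, NX)
    UX[1:ny, 1:nx] <- ux; UY[1:ny, 1:nx] <- uy
  } else {
    NY <- ny; NX <- nx; UX <- ux; UY <- uy
  }
  G <- greens_grids(NY, NX, grid_spacing_um, E_pa, nu)
  ## GtG (G symmetric), per mode
  A11 <- G$G11^2 + G$G12^2
  A12 <- G$G12 * (G$G11 + G$G22)
  A22 <- G$G22^2 + G$G12^2
  nz <- is.finite(G$K)
  s <- mean((A11[nz] + A22[nz]) / 2)
  if (lambda == 0) {
    detA <- A11 * A22 - A12^2
    if (min(detA[nz]) < 1e-12 * s^2)
      stopf("ill-conditioned inversion at lambda = 0; use lambda > 0")
  }
  Fux <- stats::fft(UX); Fuy <- stats::fft(UY)
  r1 <- G$G11 * Fux + G$G12 * Fuy
  r2 <- G$G12 * Fux + G$G22 * Fuy
  M11 <- A11 + lambda^2 * s
  M12 <- A12
  M22 <- A22 + lambda^2 * s
  det <- M11 * M22 - M12^2
  T1 <- (M22 * r1 - M12 * r2) / det
  T2 <- (M11 * r2 - M12 * r1) / det
  T1[1, 1] <- 0; T2[1, 1] <- 0
  tx <- Re(stats::fft(T1, inverse = TRUE)) / (NY * NX)
  ty <- Re(stats::fft(T2, inverse = TRUE)) / (NY * NX)
  if (pad) { tx <- tx[1:ny, 1:nx]; ty <- ty[1:ny, 1:nx] }
  out <- traction_field(tx, ty, grid_spacing_um, E_pa, nu, lambda,
                        x_px = x_px, y_px = y_px)
  attr(out, "fraction_filled") <- frac
  out
}

#' ROI traction statistics
#'
#' Arithmetic mean and maximum of the traction magnitude over the nodes
#' inside a region of interest, together with the component-wise vector sum
#' and a magnitude-weighted radial histogram of the in-ROI traction vectors
#' (same construction as for filament orientation vectors).
#'
#' @param tf a [traction_field()].
#' @param roi_mask logical matrix matching the traction grid.
#' @param n_bins radial histogram bin count.
#' @return list: `mean_pa`, `max_pa`, `sum_vector_pa`, `n_nodes`,
#'   `histogram` (see [radial_histogram()]).
#' @export
roi_traction_stats <- function(tf, roi_mask, n_bins = 24L) {
  stopifnot(inherits(tf, "traction_field"))
  if (!all(dim(roi_mask) == dim(tf$tx))) stopf("ROI mask does not match grid")
  if (!any(roi_mask)) stopf("empty ROI")
  vx <- tf$tx[roi_mask]; vy <- tf$ty[roi_mask]
  mag <- sqrt(vx^2 + vy^2)
  list(mean_pa = mean(mag), max_pa = max(mag),
       sum_vector_pa = c(sum(vx), sum(vy)),
       n_nodes = sum(roi_mask),
       histogram = radial_histogram(cbind(vx, vy), n_bins = n_bins))
}

#' Regularization parameter sweep (L-curve helper)
#'
#' Reconstructs the traction field over a grid of `lambda` values and
#' tabulates the residual norm \eqn{\|\hat G \hat t - \hat u\|} against the
#' solution norm \eqn{\|t\|}, the classical L-curve. The suggested value
#' maximizes the curvature of the log-log L-curve (corner criterion).
#'
#' @inheritParams reconstruct_traction
#' @param lambdas vector of candidate dimensionless regularization values.
#' @return data frame with columns `lambda`, `residual_norm`,
#'   `solution_norm`; attribute `suggested` holds the corner lambda.
#' @export
lambda_sweep <- function(displacement, grid_spacing_um = NULL, E_pa = 11000,
                         nu = 0.5, lambdas = 10^seq(-1, 1, by = 0.5),
                         pad = TRUE) {
  res <- lapply(lambdas, function(l) {
    tf <- reconstruct_traction(displacement, grid_spacing_um, E_pa, nu, l, pad)
    fwd <- forward_displacement(tf$tx, tf$ty, tf$grid_spacing_um, E_pa, nu)
    ux <- if (inherits(displacement, "vector_field"))
      fill_invalid_field(displacement)$u else displacement$ux
    uy <- if (inherits(displacement, "vector_field"))
      fill_invalid_field(displacement)$v else displacement$uy
    c(residual = sqrt(mean((fwd$ux - ux)^2 + (fwd$uy - uy)^2)),
      norm = sqrt(mean(tf$tx^2 + tf$ty^2)))
  })
  tab <- data.frame(lambda = lambdas,
                    residual_norm = vapply(res, `[[`, 0, "residual"),
                    solution_norm = vapply(res, `[[`, 0, "norm"))
  ## discrete curvature of the log-log L-curve
  lr <- log(pmax(tab$residual_norm, 1e-300))
  ln <- log(pmax(tab$solution_norm, 1e-300))
  curv <- rep(NA_real_, nrow(tab))
  for (i in 2:(nrow(tab) - 1)) {
    v1 <- c(lr[i] - lr[i - 1], ln[i] - ln[i - 1])
    v2 <- c(lr[i + 1] - lr[i], ln[i + 1] - ln[i])
    cr <- v1[1] * v2[2] - v1[2] * v2[1]
    curv[i] <- cr / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)) + 1e-300)
  }
  best <- if (all(is.na(curv))) ceiling(nrow(tab) / 2) else which.max(curv)
  attr(tab, "suggested") <- tab$lambda[best]
  tab
}
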