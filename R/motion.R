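#' Keratin flow field between two frames
#'
#' Windowed normalized cross-correlation between consecutive time-lapse
#' frames (the classical cross-correlation flow approach): each
#' interrogation window yields one displacement vector from the correlation
#' peak with a 3-point Gaussian subpixel fit, divided by the frame interval
#' and converted to um/min. Featureless windows and normalized-median-test
#' outliers are flagged invalid; windows whose center lies outside the mask
#' are invalid too.
#'
#' @param frame_a,frame_b consecutive frames: matrices, or 3D `(z, y, x)`
#'   arrays / [image_stack]s (maximum-projected along z).
#' @param window_px interrogation window, px (>= 16; default 32).
#' @param overlap window overlap fraction (default 0.5).
#' @param mask optional logical matrix restricting the analysis.
#' @param dt_min frame interval, minutes.
#' @param pixel_size_um lateral pixel size, um/px.
#' @param mask_coverage `"full"` (default) invalidates windows whose
#'   footprint is not entirely inside the mask: partially covered windows mix
#'   specimen motion with empty background and report biased magnitudes.
#'   `"center"` only requires the window center to be inside.
#' @return a [vector_field()] in um/min.
#' @export
compute_flow_field <- function(frame_a, frame_b, window_px = 32L,
                               overlap = 0.5, mask = NULL, dt_min = 1,
                               pixel_size_um = 0.23,
                               mask_coverage = c("full", "center")) {
  check_positive(dt_min, "dt_min")
  mask_coverage <- match.arg(mask_coverage)
  if (!is.null(mask) && mask_coverage == "full")
    mask <- erode_mask(mask, window_px / 2)
  proj <- function(f) {
    if (inherits(f, "image_stack")) f <- f$voxels
    if (is.matrix(f)) return(f)
    if (length(dim(f)) == 3L) return(apply(f, c(2, 3), max))
    stopf("frames must be matrices or (z,y,x) arrays")
  }
  a <- proj(frame_a); b <- proj(frame_b)
  vf <- piv_core(a, b, window_px, overlap, mask)
  vf$u <- vf$u * pixel_size_um / dt_min
  vf$v <- vf$v * pixel_size_um / dt_min
  vf$units <- "um_min"
  vf$pixel_size_um <- pixel_size_um
  vf
}

#' Mean keratin flow rate and radial profile
#'
#' Averages the vector magnitude over all valid in-mask windows of one or
#' several flow fields and bins the per-window rates by distance from the
#' pattern center (the radial profile; in confined keratinocytes flow is
#' fastest at the periphery).
#'
#' @param flow_fields a [vector_field()] or list of them (um/min).
#' @param mask optional logical matrix; windows outside are ignored.
#' @param center_px pattern center `c(x, y)` for the radial profile
#'   (defaults to the field's grid center).
#' @param n_radial_bins number of radial bins.
#' @return list: `mean_rate_um_min`, `n_valid`, `fraction_invalid`,
#'   `radial_profile` (data frame: r_px, rate_um_min, n),
#'   `per_window` (data frame of all pooled valid vectors).
#' @export
mean_flow_rate <- function(flow_fields, mask = NULL, center_px = NULL,
                           n_radial_bins = 6) {
  if (inherits(flow_fields, "vector_field")) flow_fields <- list(flow_fields)
  if (!length(flow_fields)) stopf("need at least one flow field")
  pooled <- NULL
  n_tot <- 0; n_valid <- 0
  for (vf in flow_fields) {
    df <- as.data.frame(vf)
    if (!is.null(mask)) {
      inm <- mask[cbind(round(df$y_px) + 1L, round(df$x_px) + 1L)]
      df$valid <- df$valid & inm
    }
    n_tot <- n_tot + nrow(df)
    n_valid <- n_valid + sum(df$valid)
    pooled <- rbind(pooled, df[df$valid, ])
  }
  if (!nrow(pooled)) stopf("no valid vectors")
  pooled$rate <- sqrt(pooled$u^2 + pooled$v^2)
  center_px <- center_px %||% c(mean(flow_fields[[1]]$x_px),
                                mean(flow_fields[[1]]$y_px))
  pooled$r_px <- sqrt((pooled$x_px - center_px[1])^2 +
                        (pooled$y_px - center_px[2])^2)
  br <- seq(0, max(pooled$r_px) * 1.0001, length.out = n_radial_bins + 1)
  bin <- cut(pooled$r_px, br, include.lowest = TRUE)
  prof <- data.frame(
    r_px = (br[-1] + br[-length(br)]) / 2,
    rate_um_min = as.numeric(tapply(pooled$rate, bin, mean)),
    n = as.integer(table(bin)))
  list(mean_rate_um_min = mean(pooled$rate),
       n_valid = n_valid,
       fraction_invalid = 1 - n_valid / n_tot,
       radial_profile = prof,
       per_window = pooled)
}

## Per-window structure tensor (summed gradient outer products). The tensor
## encodes how well window texture constrains each motion component: a
## single straight filament constrains only the normal direction (aperture
## problem), and its tensor is correspondingly rank deficient.
window_structure_tensor <- function(frame, x_px, y_px, window_px,
                                    sigma_px = 1.5) {
  g0 <- gauss_kernel(sigma_px); g1 <- gauss_kernel(sigma_px, 1L)
  Ix <- sep_filter(frame, g0, g1)
  Iy <- sep_filter(frame, g1, g0)
  Jxx_full <- Ix * Ix; Jyy_full <- Iy * Iy; Jxy_full <- Ix * Iy
  d <- c(length(y_px), length(x_px))
  Jxx <- array(0, d); Jyy <- array(0, d); Jxy <- array(0, d)
  h <- window_px / 2
  for (iy in seq_along(y_px)) for (ix in seq_along(x_px)) {
    ys <- max(1, round(y_px[iy] - h) + 1):min(nrow(frame), round(y_px[iy] + h))
    xs <- max(1, round(x_px[ix] - h) + 1):min(ncol(frame), round(x_px[ix] + h))
    Jxx[iy, ix] <- sum(Jxx_full[ys, xs])
    Jyy[iy, ix] <- sum(Jyy_full[ys, xs])
    Jxy[iy, ix] <- sum(Jxy_full[ys, xs])
  }
  list(xx = Jxx, xy = Jxy, yy = Jyy)
}

## Intensity centroid of each interrogation window (background-subtracted).
## A PIV vector reports the motion of the texture inside its window; near the
## edge of the specimen that texture is off-center, so model fits attribute
## the vector to the centroid rather than the geometric window center.
window_centroids <- function(frame, x_px, y_px, window_px) {
  bg <- stats::median(frame)
  W <- pmax(frame - bg, 0)
  h <- window_px / 2
  cxm <- matrix(NA_real_, length(y_px), length(x_px))
  cym <- cxm
  for (iy in seq_along(y_px)) for (ix in seq_along(x_px)) {
    ys <- max(1, round(y_px[iy] - h) + 1):min(nrow(frame), round(y_px[iy] + h))
    xs <- max(1, round(x_px[ix] - h) + 1):min(ncol(frame), round(x_px[ix] + h))
    w <- W[ys, xs]
    tot <- sum(w)
    if (tot > 0) {
      cym[iy, ix] <- sum(rowSums(w) * (ys - 1)) / tot
      cxm[iy, ix] <- sum(colSums(w) * (xs - 1)) / tot
    } else {
      cym[iy, ix] <- y_px[iy]; cxm[iy, ix] <- x_px[ix]
    }
  }
  list(x = cxm, y = cym)
}

#' Rotation rate of a confined cell group
#'
#' Runs PIV between consecutive frames of a time series and converts the
#' tangential velocity component around the pattern center into an angular
#' velocity, averaged over windows with radius-squared weights
#' (inverse-variance weighting of the per-window tangential/radius ratio).
#' Sign convention: positive = anticlockwise in the Cartesian (y-up) sense.
#'
#' @param series a `flow_series`, a 4D `(t, z, y, x)` [image_stack], or a
#'   list of frames (matrices).
#' @param center_px rotation center `c(x, y)`, 0-based px.
#' @param dt_min frame interval, minutes (taken from the stack if present).
#' @param window_px,overlap PIV settings.
#' @param mask optional logical matrix; the center must lie inside it.
#' @param min_radius_px windows closer to the center are ignored.
#' @return list: `omega_deg_h` (signed), `sign`, `per_pair` (deg/h per frame
#'   pair), `mean_field` (average displacement [vector_field()], px/frame).
#' @details The angular velocity is obtained by weighted least squares: the
#'   rigid-rotation model displacement is fitted to the PIV vectors with each
#'   window's structure tensor as the weight metric (normal-flow weighting).
#'   A window dominated by a single straight filament only constrains the
#'   motion component normal to it (aperture problem); its structure tensor
#'   is near rank-one and automatically discards the unobservable component,
#'   which would otherwise bias the tangential estimate low.
#' @export
rotation_rate <- function(series, center_px, dt_min = NULL, window_px = 32L,
                          overlap = 0.5, mask = NULL, min_radius_px = 8) {
  frames <- NULL
  if (inherits(series, "flow_series")) series <- series$stack
  if (inherits(series, "image_stack")) {
    dt_min <- dt_min %||% series$dt_min
    v <- series$voxels
    if (length(dim(v)) != 4L) stopf("need a (t,z,y,x) time series")
    frames <- lapply(seq_len(dim(v)[1]), function(t)
      apply(v[t, , , , drop = FALSE][1, , , ], c(2, 3), max))
  } else if (is.list(series)) {
    frames <- series
  }
  if (length(frames) < 2) stopf("need at least 2 frames")
  check_positive(dt_min %||% stop("dt_min required"), "dt_min")
  if (!is.null(mask)) {
    if (!mask[round(center_px[2]) + 1L, round(center_px[1]) + 1L])
      stopf("center lies outside the mask")
  }
  ## only windows fully inside the mask: partially covered windows see the
  ## static pattern rim, which is rotation-invariant and biases toward zero
  mask_strict <- if (!is.null(mask)) erode_mask(mask, window_px / 2 + 1) else NULL
  omega <- numeric(0)
  Usum <- NULL; Vsum <- NULL; Nsum <- NULL
  ref_field <- NULL
  for (t in seq_len(length(frames) - 1)) {
    vf <- piv_core(frames[[t]], frames[[t + 1]], window_px, overlap, mask_strict)
    J <- window_structure_tensor(frames[[t]], vf$x_px, vf$y_px, window_px)
    cen <- window_centroids(frames[[t]], vf$x_px, vf$y_px, window_px)
    if (is.null(Usum)) {
      Usum <- matrix(0, nrow(vf$u), ncol(vf$u)); Vsum <- Usum; Nsum <- Usum
      ref_field <- vf
    }
    ok <- vf$valid
    Usum[ok] <- Usum[ok] + vf$u[ok]
    Vsum[ok] <- Vsum[ok] + vf$v[ok]
    Nsum[ok] <- Nsum[ok] + 1
    gx <- as.vector(cen$x)
    gy <- as.vector(cen$y)
    rx <- gx - center_px[1]
    ry_px <- gy - center_px[2]
    r <- sqrt(rx^2 + ry_px^2)
    okv <- as.vector(ok) & r >= min_radius_px
    if (!is.null(mask_strict)) {
      inm <- mask_strict[cbind(round(gy) + 1L, round(gx) + 1L)]
      okv <- okv & inm
    }
    if (!any(okv)) { omega <- c(omega, NA_real_); next }
    ## rigid-rotation model in pixel coordinates for math-positive
    ## (anticlockwise, y-up) omega: d = omega * (y - cy, -(x - cx))
    ax <- ry_px; ay <- -rx
    u <- as.vector(vf$u); v <- as.vector(vf$v)
    jxx <- as.vector(J$xx); jxy <- as.vector(J$xy); jyy <- as.vector(J$yy)
    num <- sum((ax * (jxx * u + jxy * v) + ay * (jxy * u + jyy * v))[okv])
    den <- sum((ax^2 * jxx + 2 * ax * ay * jxy + ay^2 * jyy)[okv])
    if (den <= 0) { omega <- c(omega, NA_real_); next }
    om_rad <- num / den                                    # rad per frame
    omega <- c(omega, om_rad * 180 / pi * 60 / dt_min)     # deg per hour
  }
  mean_field <- ref_field
  mean_field$u <- Usum / pmax(Nsum, 1)
  mean_field$v <- Vsum / pmax(Nsum, 1)
  mean_field$valid <- Nsum > 0
  mean_field$units <- "px_frame"
  om <- mean(omega, na.rm = TRUE)
  list(omega_deg_h = om, sign = sign(om), per_pair = omega,
       mean_field = mean_field)
}
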