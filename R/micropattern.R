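#' Micropattern geometry and binary mask
#'
#' Builds the binary adhesive-island mask used to confine simulated cells and
#' to restrict analyses to the patterned area. Supported shapes follow common
#' micropatterning layouts for keratinocytes: a full disc (e.g. the 47 um
#' circles used for rotational migration assays), a D-shape (a disc cut by a
#' chord through its center, mimicking the outline of a polarized migrating
#' cell), and an axis-aligned stripe (e.g. 20 um wide lanes).
#'
#' Coordinates are 0-based pixel indices with pixel centers at integer
#' positions; the mask is stored as a `ny x nx` logical matrix indexed
#' `[y, x]`.
#'
#' @param shape one of `"disc"`, `"D"`, `"stripe"`.
#' @param diameter_um pattern diameter in micrometers (disc and D). For a
#'   stripe this is ignored; the band spans the full image width.
#' @param pixel_size_um lateral pixel size in micrometers per pixel.
#' @param image_shape integer vector `c(ny, nx)` of the target frame in pixels.
#' @param center_px optional pattern center `c(x, y)` in 0-based pixels;
#'   defaults to the frame center.
#' @param stripe_width_um stripe width in micrometers (stripe only).
#' @param flat_fraction for the D-shape, position of the flat chord as a
#'   fraction of the radius measured from the center towards the flat side;
#'   0 (default) cuts through the center giving a half-disc.
#' @return an object of class `micropattern`: a list with the geometry fields
#'   and a logical `mask` matrix.
#' @examples
#' mp <- make_micropattern("disc", diameter_um = 47, pixel_size_um = 0.23,
#'                         image_shape = c(256, 256))
#' sum(mp$mask) * mp$pixel_size_um^2  # close to pi * (47/2)^2
#' @export
make_micropattern <- function(shape = c("disc", "D", "stripe"),
                              diameter_um = 47,
                              pixel_size_um = 0.23,
                              image_shape = c(256L, 256L),
                              center_px = NULL,
                              stripe_width_um = NULL,
                              flat_fraction = 0) {
  shape <- match.arg(shape)
  check_positive(pixel_size_um, "pixel_size_um")
  ny <- as.integer(image_shape[1]); nx <- as.integer(image_shape[2])
  if (ny < 2 || nx < 2) stopf("image_shape must be at least 2 x 2 pixels")
  center_px <- center_px %||% c((nx - 1) / 2, (ny - 1) / 2)
  cx <- center_px[1]; cy <- center_px[2]

  X <- matrix(rep(seq_len(nx) - 1, each = ny), ny, nx)
  Y <- matrix(rep(seq_len(ny) - 1, nx), ny, nx)

  if (shape %in% c("disc", "D")) {
    check_positive(diameter_um, "diameter_um")
    r_px <- diameter_um / 2 / pixel_size_um
    if (cx - r_px < 0 || cx + r_px > nx - 1 || cy - r_px < 0 || cy + r_px > ny - 1)
      stopf("pattern of diameter %.3g um (radius %.1f px) does not fit in a %d x %d frame",
            diameter_um, r_px, ny, nx)
    mask <- (X - cx)^2 + (Y - cy)^2 <= r_px^2
    if (shape == "D") {
      if (abs(flat_fraction) >= 1)
        stopf("flat_fraction must lie in (-1, 1)")
      ## flat edge on the left: keep x >= cx - flat_fraction * r
      mask <- mask & (X >= cx - flat_fraction * r_px)
    }
  } else {
    check_positive(stripe_width_um %||% stop("stripe_width_um required for stripe"),
                   "stripe_width_um")
    w_px <- round(stripe_width_um / pixel_size_um)
    if (w_px < 1) stopf("stripe narrower than one pixel")
    y0 <- round(cy - w_px / 2)
    if (y0 < 0 || y0 + w_px > ny)
      stopf("stripe of %d rows does not fit in a %d-row frame", w_px, ny)
    mask <- matrix(FALSE, ny, nx)
    mask[(y0 + 1):(y0 + w_px), ] <- TRUE
  }

  structure(list(shape = shape,
                 diameter_um = if (shape == "stripe") NA_real_ else diameter_um,
                 stripe_width_um = if (shape == "stripe") stripe_width_um else NA_real_,
                 center_px = c(cx, cy),
                 pixel_size_um = pixel_size_um,
                 image_shape = c(ny, nx),
                 mask = mask),
            class = "micropattern")
}

#' @export
print.micropattern <- function(x, ...) {
  cat(sprintf("<micropattern> %s, %s, %.3g um/px, frame %d x %d, area %d px\n",
              x$shape,
              if (x$shape == "stripe") sprintf("width %.3g um", x$stripe_width_um)
              else sprintf("diameter %.3g um", x$diameter_um),
              x$pixel_size_um, x$image_shape[1], x$image_shape[2], sum(x$mask)))
  invisible(x)
}

## Morphological erosion of a logical mask by a disc of radius r_px,
## via FFT convolution with the complement.
erode_mask <- function(mask, r_px) {
  if (r_px <= 0) return(mask)
  ny <- nrow(mask); nx <- ncol(mask)
  r <- ceiling(r_px)
  k <- outer(seq(-r, r)^2, seq(-r, r)^2, `+`) <= r_px^2
  bg <- 1 - mask
  ## zero-padded convolution counting background pixels within the disc
  py <- ny + 2 * r; px <- nx + 2 * r
  A <- matrix(0, py, px); A[(r + 1):(r + ny), (r + 1):(r + nx)] <- bg
  ## treat outside-frame as background so erosion also retracts from borders
  A[1:r, ] <- 1; A[(r + ny + 1):py, ] <- 1
  A[, 1:r] <- 1; A[, (r + nx + 1):px] <- 1
  K <- matrix(0, py, px)
  K[1:(2 * r + 1), 1:(2 * r + 1)] <- k
  conv <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (py * px)
  core <- conv[(2 * r + 1):(2 * r + ny), (2 * r + 1):(2 * r + nx)]
  mask & (core < 0.5)
}
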