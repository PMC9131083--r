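#' Image stack container
#'
#' Thin S3 container for fluorescence image data: a numeric array in fixed
#' `(z, y, x)` order (or `(t, z, y, x)` for time series) plus the physical
#' metadata every downstream stage needs. Intensities must be finite and
#' nonnegative.
#'
#' @param voxels numeric array, `(z, y, x)` or `(t, z, y, x)`; a plain matrix
#'   is promoted to a single-plane stack.
#' @param pixel_size_um lateral pixel size (um/px).
#' @param z_step_um axial plane spacing (um); ignored for single-plane data.
#' @param dt_min frame interval in minutes (time series only).
#' @param channel free-text channel label.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_size_um = 0.23, z_step_um = 0.5,
                        dt_min = NA_real_, channel = "keratin") {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, dim(voxels)))
  nd <- length(dim(voxels))
  if (!nd %in% c(3L, 4L)) stopf("voxels must be a (z,y,x) or (t,z,y,x) array")
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stopf("voxel intensities must be finite")
  if (any(voxels < 0)) stopf("voxel intensities must be nonnegative")
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(z_step_um, "z_step_um")
  structure(list(voxels = voxels, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um, dt_min = dt_min, channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %s [%s], %.3g um/px, z-step %.3g um%s\n",
              x$channel, paste(d, collapse = " x "), x$pixel_size_um,
              x$z_step_um,
              if (is.finite(x$dt_min)) sprintf(", dt %.3g min", x$dt_min) else ""))
  invisible(x)
}

## single 2D plane accessor (first z / first t)
stack_plane <- function(stack, z = 1L, t = NULL) {
  v <- stack$voxels
  if (length(dim(v)) == 4L) v[t %||% 1L, z, , ] else v[z, , ]
}

n_frames <- function(stack) {
  if (length(dim(stack$voxels)) == 4L) dim(stack$voxels)[1] else 1L
}

#' Read / write image stacks as multi-page TIFF
#'
#' Stacks are written as multi-page TIFF (one page per z-plane, time-major for
#' hyperstacks) with the physical metadata in a JSON sidecar file
#' (`<path>.json`). Integer-valued stacks up to 16 bit are stored losslessly
#' as 16-bit pages; continuous data are stored as 32-bit pages scaled by the
#' stack maximum (the scale is recorded in the sidecar, giving a relative
#' round-trip precision of 2^-32). On read, the sidecar is used when present;
#' otherwise metadata falls back to the supplied defaults with a warning.
#'
#' @param path TIFF file path.
#' @param pixel_size_um,z_step_um,dt_min fallback metadata used when no
#'   sidecar file is found.
#' @return `read_stack` returns an [image_stack]; `write_stack` returns
#'   `path` invisibly.
#' @export
read_stack <- function(path, pixel_size_um = 0.23, z_step_um = 0.5,
                       dt_min = NA_real_) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  meta_path <- paste0(path, ".json")
  dims <- NULL
  channel <- "unknown"
  scale <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    pixel_size_um <- meta$pixel_size_um %||% pixel_size_um
    z_step_um <- meta$z_step_um %||% z_step_um
    dt_min <- meta$dt_min %||% dt_min
    channel <- meta$channel %||% channel
    dims <- meta$dims
    scale <- meta$intensity_scale
  } else {
    warning(sprintf("no metadata sidecar for %s; using fallback pixel size %g um",
                    path, pixel_size_um), call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = is.null(scale))
  if (!is.list(pages)) pages <- list(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  flat <- vapply(pages, function(p) as.numeric(t(p)), numeric(ny * nx))
  if (is.null(dims)) dims <- c(length(pages), ny, nx)
  ## pages are stored x-fastest; rebuild as (..., z, y, x)
  arr <- aperm(array(flat, c(nx, ny, length(pages))), c(3, 2, 1))
  if (!is.null(scale)) arr <- arr * scale
  voxels <- array(arr, dims)
  image_stack(voxels, pixel_size_um, z_step_um, dt_min, channel)
}

#' @param stack an [image_stack].
#' @rdname read_stack
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  d <- dim(v)
  pages_arr <- array(v, c(prod(d) / (d[length(d) - 1] * d[length(d)]),
                          d[length(d) - 1], d[length(d)]))
  pages <- lapply(seq_len(dim(pages_arr)[1]),
                  function(i) pages_arr[i, , ])
  integerish <- all(v == round(v)) && max(v) <= 65535
  if (integerish) {
    tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                    bits.per.sample = 16L)
    scale <- NULL
  } else {
    scale <- max(v, 1e-300)
    tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                    bits.per.sample = 32L)
  }
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size_um, z_step_um = stack$z_step_um,
         dt_min = stack$dt_min, channel = stack$channel, dims = d,
         intensity_scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Denoise an image stack
#'
#' Classical denoising applied plane by plane, used as the default
#' preprocessing stage before ridge enhancement and centerline extraction.
#' Externally restored stacks (e.g. output of a trained content-aware
#' restoration model) can be passed through untouched with `method = "none"`.
#'
#' @param stack an [image_stack].
#' @param method `"gaussian"` (default, sigma in px), `"median"` (square
#'   window, radius in px), `"rl_deconv"` (Richardson-Lucy deconvolution with
#'   a Gaussian PSF), or `"none"`.
#' @param sigma_px Gaussian sigma or PSF sigma, pixels.
#' @param radius_px median window radius, pixels.
#' @param iterations Richardson-Lucy iteration count.
#' @return a denoised [image_stack] of identical shape.
#' @export
denoise_stack <- function(stack, method = c("gaussian", "median", "rl_deconv", "none"),
                          sigma_px = 1, radius_px = 1L, iterations = 10L) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  if (method == "none") return(stack)
  out <- stack
  apply_plane <- function(m) {
    switch(method,
      gaussian = gauss_blur2d(m, sigma_px),
      median   = median_filter2d(m, radius_px),
      rl_deconv = rl_deconvolve2d(m, sigma_px, iterations))
  }
  v <- stack$voxels
  d <- dim(v)
  flat <- array(v, c(prod(d) / (d[length(d) - 1] * d[length(d)]),
                     d[length(d) - 1], d[length(d)]))
  for (i in seq_len(dim(flat)[1])) flat[i, , ] <- apply_plane(flat[i, , ])
  out$voxels <- array(flat, d)
  out$voxels[out$voxels < 0] <- 0
  out
}

median_filter2d <- function(m, r) {
  r <- as.integer(r)
  p <- pad_reflect(m, r)
  ny <- nrow(m); nx <- ncol(m)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  stacked <- vapply(seq_len(nrow(offs)), function(i) {
    p[(r + 1 + offs$dy[i]):(r + ny + offs$dy[i]),
      (r + 1 + offs$dx[i]):(r + nx + offs$dx[i])]
  }, matrix(0, ny, nx))
  apply(stacked, c(1, 2), stats::median)
}

rl_deconvolve2d <- function(m, sigma_px, iterations) {
  est <- pmax(m, 1e-8)
  blur <- function(x) gauss_blur2d(x, sigma_px)
  for (i in seq_len(iterations)) {
    conv <- pmax(blur(est), 1e-8)
    est <- est * blur(m / conv)
  }
  est
}

#' Drift alignment of an image pair by phase correlation
#'
#' Estimates the global translation between a reference and a moving frame by
#' whole-frame phase correlation, refined to subpixel precision with a
#' matrix-multiply discrete Fourier transform evaluated on an upsampled grid
#' around the integer peak. Serves the same purpose as template-matching the
#' stressed against the relaxed bead frame before traction analysis.
#'
#' @param reference,moving equal-size numeric matrices.
#' @param upsample_factor subpixel refinement factor (1 = integer precision).
#' @return list with `shift` (`c(dx, dy)` in px: the displacement of `moving`
#'   relative to `reference`), `aligned` (moving shifted by `-shift`,
#'   edge-filled with the image median) and `degenerate` flag.
#' @export
align_drift <- function(reference, moving, upsample_factor = 10) {
  if (inherits(reference, "image_stack")) reference <- stack_plane(reference)
  if (inherits(moving, "image_stack")) moving <- stack_plane(moving)
  if (!all(dim(reference) == dim(moving))) stopf("images must have equal shapes")
  ny <- nrow(reference); nx <- ncol(reference)
  a <- reference - mean(reference); b <- moving - mean(moving)
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
    warning("degenerate (constant) image: returning zero shift", call. = FALSE)
    return(list(shift = c(0, 0), aligned = moving, degenerate = TRUE))
  }
  FA <- stats::fft(a); FB <- stats::fft(b)
  R <- FB * Conj(FA)
  ## spectrally weighted phase correlation: full whitening would amplify
  ## noise-dominated frequencies; the regularizer keeps the peak sharp while
  ## suppressing them, and is exact for clean translations
  R <- R / (Mod(R) + 1e-6 * max(Mod(R)))
  cc <- Re(stats::fft(R, inverse = TRUE))
  peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  dy <- peak[1] - 1; dx <- peak[2] - 1
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  if (upsample_factor > 1) {
    ## upsampled DFT of the cross-power spectrum in a 3x3 px neighborhood
    uf <- upsample_factor
    span <- 1.5
    dyg <- dy + seq(-span, span, by = 1 / uf)
    dxg <- dx + seq(-span, span, by = 1 / uf)
    fy <- fft_freq(ny); fx <- fft_freq(nx)
    Ey <- exp(2i * pi * outer(dyg, fy))        # |dyg| x ny
    Ex <- exp(2i * pi * outer(fx, dxg))        # nx x |dxg|
    cc_up <- Re(Ey %*% R %*% Ex)
    pk <- which(cc_up == max(cc_up), arr.ind = TRUE)[1, ]
    dy <- dyg[pk[1]]; dx <- dxg[pk[2]]
  }
  shifted <- fourier_shift(moving, -dx, -dy)
  ## fill wrapped-in margins with the image median
  med <- stats::median(moving)
  if (dx > 0) shifted[, max(1, nx - ceiling(dx) + 1):nx] <- med
  if (dx < 0) shifted[, 1:min(nx, ceiling(-dx))] <- med
  if (dy > 0) shifted[max(1, ny - ceiling(dy) + 1):ny, ] <- med
  if (dy < 0) shifted[1:min(ny, ceiling(-dy)), ] <- med
  list(shift = c(dx, dy), aligned = shifted, degenerate = FALSE)
}
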