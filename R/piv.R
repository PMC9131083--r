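#' Vector field on a regular interrogation grid
#'
#' Result container for windowed cross-correlation (PIV) analyses: a regular
#' grid of 2D vectors with a validity flag per window. Invalid windows
#' (featureless, low correlation, or median-test outliers) are excluded from
#' every aggregate computed downstream.
#'
#' @param x_px,y_px grid center coordinates (0-based px) along x and y.
#' @param u,v vector components, matrices `[y, x]` in `units`.
#' @param valid logical matrix of the same shape.
#' @param units unit label (`"px"`, `"um"`, `"um_min"`).
#' @param window_px,overlap interrogation window size and overlap fraction.
#' @param pixel_size_um lateral pixel size the field was computed with.
#' @return an object of class `vector_field`.
#' @export
vector_field <- function(x_px, y_px, u, v, valid, units = "px",
                         window_px = NA, overlap = NA, pixel_size_um = NA) {
  stopifnot(is.matrix(u), all(dim(u) == dim(v)), all(dim(u) == dim(valid)),
            length(y_px) == nrow(u), length(x_px) == ncol(u))
  structure(list(x_px = x_px, y_px = y_px, u = u, v = v, valid = valid,
                 units = units, window_px = window_px, overlap = overlap,
                 pixel_size_um = pixel_size_um),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  cat(sprintf("<vector_field> %d x %d windows (%d px, %.0f%% overlap), %s, %d%% valid\n",
              length(x$y_px), length(x$x_px), x$window_px, 100 * x$overlap,
              x$units, round(100 * mean(x$valid))))
  invisible(x)
}

#' @export
as.data.frame.vector_field <- function(x, ...) {
  data.frame(x_px = rep(x$x_px, each = length(x$y_px)),
             y_px = rep(x$y_px, times = length(x$x_px)),
             u = as.vector(x$u), v = as.vector(x$v),
             valid = as.vector(x$valid))
}

## Mean vector magnitude over valid windows.
field_mean_magnitude <- function(vf) {
  ok <- vf$valid & is.finite(vf$u) & is.finite(vf$v)
  if (!any(ok)) stopf("no valid vectors in field")
  mean(sqrt(vf$u[ok]^2 + vf$v[ok]^2))
}

## Core windowed normalized cross-correlation between two equal-size frames.
## Returns displacement of `b` relative to `a` in pixels per window, with a
## 3-point Gaussian subpixel peak fit and normalized-median-test outlier
## invalidation.
piv_core <- function(a, b, window_px = 32L, overlap = 0.5, mask = NULL,
                     min_peak = 0.1) {
  if (!all(dim(a) == dim(b))) stopf("frames must have equal shapes")
  if (window_px < 16) stopf("window_px must be >= 16")
  ny <- nrow(a); nx <- ncol(a)
  w <- as.integer(window_px)
  if (w > min(ny, nx)) stopf("window larger than frame")
  step <- max(1L, as.integer(round(w * (1 - overlap))))
  cx <- seq(w / 2, nx - w / 2, by = step)          # 0-based window centers
  cy <- seq(w / 2, ny - w / 2, by = step)
  U <- matrix(NA_real_, length(cy), length(cx))
  V <- matrix(NA_real_, length(cy), length(cx))
  OK <- matrix(FALSE, length(cy), length(cx))
  max_shift <- floor(w / 3)
  ## linear (zero-padded) correlation on a 2w x 2w transform; per-lag
  ## normalization by the energies over the actual overlap region
  L <- 2L * w
  lag_idx <- function(d) ifelse(d >= 0, d + 1L, L + d + 1L)
  lags <- -max_shift:max_shift
  li <- lag_idx(lags)
  ones <- matrix(0, L, L); ones[1:w, 1:w] <- 1
  Fones <- stats::fft(ones)
  xcorr <- function(A, B) {
    ## C(l) = sum_i A(i) B(i+l), A and B already zero-padded to L x L
    Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE)) / (L * L)
  }
  for (iy in seq_along(cy)) for (ix in seq_along(cx)) {
    if (!is.null(mask)) {
      my <- round(cy[iy]) + 1L; mx <- round(cx[ix]) + 1L
      if (!mask[my, mx]) next
    }
    y0 <- round(cy[iy] - w / 2) + 1L
    x0 <- round(cx[ix] - w / 2) + 1L
    wa <- a[y0:(y0 + w - 1), x0:(x0 + w - 1)]
    wb <- b[y0:(y0 + w - 1), x0:(x0 + w - 1)]
    sa <- stats::sd(wa); sb <- stats::sd(wb)
    if (!is.finite(sa) || !is.finite(sb) || sa < 1e-10 || sb < 1e-10) next
    ## full per-lag zero-normalized cross-correlation: means and energies are
    ## taken over the actual overlap region of every lag
    A <- matrix(0, L, L); A[1:w, 1:w] <- wa
    B <- matrix(0, L, L); B[1:w, 1:w] <- wb
    C <- xcorr(A, B)
    Sa1 <- xcorr(A, ones);  Sb1 <- xcorr(ones, B)
    Saa <- xcorr(A * A, ones); Sbb <- xcorr(ones, B * B)
    Nl <- pmax(xcorr(ones, ones), 1)
    num <- C - Sa1 * Sb1 / Nl
    den <- sqrt(pmax((Saa - Sa1^2 / Nl) * (Sbb - Sb1^2 / Nl), 1e-20))
    ncc <- num / den
    sub <- ncc[li, li]
    pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    if (max(sub) < min_peak) next
    dy <- lags[pk[1]]; dx <- lags[pk[2]]
    ## 3-point Gaussian fit per axis on the normalized correlation plane
    val <- function(ddy, ddx) ncc[lag_idx(dy + ddy), lag_idx(dx + ddx)]
    c0 <- val(0, 0)
    eps <- 1e-12
    fit1d <- function(cm, cc0, cp) {
      if (cm > 0 && cc0 > 0 && cp > 0 && cc0 >= cm && cc0 >= cp) {
        den <- 2 * log(cm) - 4 * log(cc0) + 2 * log(cp)
        if (abs(den) > eps) return((log(cm) - log(cp)) / den)
      }
      den <- 2 * (cm - 2 * cc0 + cp)
      if (abs(den) > eps) (cm - cp) / den else 0
    }
    sy <- fit1d(val(-1, 0), c0, val(1, 0))
    sx <- fit1d(val(0, -1), c0, val(0, 1))
    if (abs(sy) > 1) sy <- 0
    if (abs(sx) > 1) sx <- 0
    U[iy, ix] <- dx + sx
    V[iy, ix] <- dy + sy
    OK[iy, ix] <- TRUE
  }
  ## normalized median test (universal outlier detection)
  OK2 <- OK
  for (iy in seq_along(cy)) for (ix in seq_along(cx)) {
    if (!OK[iy, ix]) next
    ys <- max(1, iy - 1):min(length(cy), iy + 1)
    xs <- max(1, ix - 1):min(length(cx), ix + 1)
    nbu <- U[ys, xs]; nbv <- V[ys, xs]; nbo <- OK[ys, xs]
    nbo[ys == iy, xs == ix] <- FALSE
    nbu <- nbu[nbo]; nbv <- nbv[nbo]
    if (length(nbu) < 3) next
    for (comp in 1:2) {
      vals <- if (comp == 1) nbu else nbv
      self <- if (comp == 1) U[iy, ix] else V[iy, ix]
      med <- stats::median(vals)
      res <- stats::median(abs(vals - med))
      if (abs(self - med) / (res + 0.1) > 2) { OK2[iy, ix] <- FALSE; break }
    }
  }
  vector_field(cx, cy, U, V, OK2, units = "px",
               window_px = w, overlap = overlap)
}

## Fill invalid / missing grid nodes by inverse-distance weighting of valid
## ones (needed before FTTC, which requires a complete grid).
fill_invalid_field <- function(vf) {
  ok <- vf$valid & is.finite(vf$u) & is.finite(vf$v)
  frac <- 1 - mean(ok)
  if (!any(ok)) stopf("cannot interpolate: no valid vectors")
  if (all(ok)) return(list(u = vf$u, v = vf$v, fraction_filled = 0))
  gx <- rep(seq_along(vf$x_px), each = length(vf$y_px))
  gy <- rep(seq_along(vf$y_px), times = length(vf$x_px))
  u <- vf$u; v <- vf$v
  bad <- which(!ok)
  good <- which(ok)
  for (i in bad) {
    d2 <- (gx[good] - gx[i])^2 + (gy[good] - gy[i])^2
    wgt <- 1 / pmax(d2, 1e-9)
    u[i] <- sum(wgt * vf$u[good]) / sum(wgt)
    v[i] <- sum(wgt * vf$v[good]) / sum(wgt)
  }
  list(u = u, v = v, fraction_filled = frac)
}
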