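## Internal numerical helpers shared across modules. All image matrices are
## indexed [y, x] (row = y), 0-based physical coordinates refer to pixel
## centers at integer positions (first pixel center = 0).

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stopf("'%s' must be a single positive finite number", name)
  invisible(x)
}

## 1D Gaussian kernel and its derivatives, truncated at 4 sigma.
gauss_kernel <- function(sigma, order = 0L, radius = NULL) {
  r <- radius %||% max(1L, ceiling(4 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) return(-x / sigma^2 * g)
  if (order == 2L) {
    k <- (x^2 - sigma^2) / sigma^4 * g
    return(k - mean(k))   # exact zero response on constants
  }
  stopf("unsupported derivative order %d", order)
}

## Reflect-pad a matrix by r rows/cols on each side.
pad_reflect <- function(m, ry, rx = ry) {
  ny <- nrow(m); nx <- ncol(m)
  iy <- c(rev(seq_len(min(ry, ny))), seq_len(ny), ny + 1 - seq_len(min(ry, ny)))
  if (ry > ny) iy <- rep(iy, length.out = ny + 2 * ry)  # degenerate tiny images
  ix <- c(rev(seq_len(min(rx, nx))), seq_len(nx), nx + 1 - seq_len(min(rx, nx)))
  m[iy, ix, drop = FALSE]
}

## Separable convolution of a matrix with 1D kernels along y then x,
## reflect boundary. ky/kx must have odd length.
sep_filter <- function(m, ky, kx = ky) {
  ry <- (length(ky) - 1L) %/% 2L
  rx <- (length(kx) - 1L) %/% 2L
  p <- pad_reflect(m, ry, rx)
  ## stats::filter runs down each column; kernel reversed so this is convolution
  if (ry > 0) {
    p <- stats::filter(p, rev(ky), method = "convolution", sides = 2)
    p <- p[(ry + 1):(nrow(p) - ry), , drop = FALSE]
  }
  if (rx > 0) {
    p <- t(stats::filter(t(p), rev(kx), method = "convolution", sides = 2))
    p <- p[, (rx + 1):(ncol(p) - rx), drop = FALSE]
  }
  unname(as.matrix(p))
}

gauss_blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  sep_filter(m, gauss_kernel(sigma))
}

## Integer matrix shift with zero fill; (dy, dx) moves content down/right.
shift_mat <- function(m, dy, dx, fill = 0) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- max(1, 1 + dy):min(ny, ny + dy)
  xs <- max(1, 1 + dx):min(nx, nx + dx)
  if (length(ys) && length(xs))
    out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  out
}

## Bilinear interpolation of matrix m at 0-based (x, y) positions.
## Out-of-frame queries are clamped to the border.
bilinear <- function(m, x, y) {
  ny <- nrow(m); nx <- ncol(m)
  x <- pmin(pmax(x, 0), nx - 1)
  y <- pmin(pmax(y, 0), ny - 1)
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  (1 - fy) * ((1 - fx) * m[i00] + fx * m[i01]) +
    fy * ((1 - fx) * m[i10] + fx * m[i11])
}

## FFT frequencies (cycles per sample), standard DFT ordering.
fft_freq <- function(n) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / n
}

## Subpixel image translation by (dx, dy) pixels via Fourier shift theorem.
fourier_shift <- function(m, dx, dy) {
  ny <- nrow(m); nx <- ncol(m)
  fy <- fft_freq(ny); fx <- fft_freq(nx)
  ph <- exp(-2i * pi * (outer(fy * dy, rep(1, nx)) + outer(rep(1, ny), fx * dx)))
  Re(stats::fft(stats::fft(m) * ph, inverse = TRUE)) / (ny * nx)
}

## Resample an ordered polyline (n x d matrix) at uniform arc-length spacing.
resample_polyline <- function(P, ds) {
  P <- as.matrix(P)
  seglen <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  keep <- c(TRUE, seglen > 0)
  P <- P[keep, , drop = FALSE]
  if (nrow(P) < 2) return(P)
  s <- c(0, cumsum(sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))))
  L <- s[length(s)]
  n_out <- max(2L, floor(L / ds) + 1L)
  si <- seq(0, L, length.out = n_out)
  out <- vapply(seq_len(ncol(P)),
                function(j) stats::approx(s, P[, j], xout = si)$y,
                numeric(n_out))
  matrix(out, nrow = n_out)
}

polyline_arclength <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) < 2) return(0)
  sum(sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2)))
}

## Minimum distance from each query point (n x d) to a polyline (m x d),
## using true point-to-segment distances.
dist_to_polyline <- function(Q, P) {
  Q <- as.matrix(Q); P <- as.matrix(P)
  if (nrow(P) == 1)
    return(sqrt(rowSums((Q - matrix(P, nrow(Q), ncol(P), byrow = TRUE))^2)))
  best <- rep(Inf, nrow(Q))
  for (i in seq_len(nrow(P) - 1)) {
    a <- P[i, ]; b <- P[i + 1, ]
    ab <- b - a
    ab2 <- sum(ab^2)
    d <- sweep(Q, 2, a)
    t <- if (ab2 > 0) pmin(pmax(as.vector(d %*% ab) / ab2, 0), 1) else 0
    proj <- d - outer(t, ab)
    best <- pmin(best, sqrt(rowSums(proj^2)))
  }
  best
}
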