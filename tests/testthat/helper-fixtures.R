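## Shared fixtures, generated in code at test time.

PIXEL <- 0.23  # um/px, default camera calibration used across fixtures

## Random bead image with ~uniform coverage; returns the matrix.
bead_image <- function(n = 256, n_beads = 2000, sigma = 1.2, amp = 100,
                       bg = 10, seed = 42) {
  set.seed(seed)
  xs <- stats::runif(n_beads, 3, n - 4)
  ys <- stats::runif(n_beads, 3, n - 4)
  keratrack:::render_beads(xs, ys, rep(amp, n_beads), n, n, sigma) + bg
}

## Small disc scene with a simulated network.
disc_scene <- function(n_curves = 15, amplitude = 50, seed = 11,
                       margin_um = 1, diameter = 47, frame = 256, ...) {
  mp <- make_micropattern("disc", diameter, PIXEL, c(frame, frame))
  net <- simulate_filament_network(mp, n_curves = n_curves,
                                   margin_um = margin_um, seed = seed, ...)
  synthetic_scene(mp, network = net, optics = list(amplitude = amplitude),
                  seed = seed)
}

## Hand-built straight filament truth spanning x0..x1 at row y (pixels).
line_truth <- function(x0_px, x1_px, y_px, z_um = 1, n = 200) {
  structure(list(
    curves = list(cbind(seq(x0_px, x1_px, length.out = n) * PIXEL,
                        rep(y_px * PIXEL, n), rep(z_um, n))),
    profiles = list(rep(1, n)), amplitude = 1,
    particles = matrix(numeric(0), 0, 3), seed = 1L),
    class = "filament_truth")
}

## Analytic dipole traction field on an n x n grid with spacing h (um).
dipole_grids <- function(n = 256, h = PIXEL, width_um = 8, amp_pa = 500,
                         sep_um = 24) {
  x <- (0:(n - 1)) * h
  X <- matrix(rep(x, each = n), n, n); Y <- matrix(rep(x, n), n, n)
  cx <- max(x) / 2
  g1 <- exp(-((X - cx - sep_um / 2)^2 + (Y - cx)^2) / (2 * width_um^2))
  g2 <- exp(-((X - cx + sep_um / 2)^2 + (Y - cx)^2) / (2 * width_um^2))
  list(tx = amp_pa * (g2 - g1), ty = matrix(0, n, n), h = h)
}

## Brute-force single-linkage node partition (O(n^2) oracle): canonical
## string of sorted global vertex ids per node.
brute_force_nodes <- function(segs, eps_um) {
  V <- do.call(rbind, lapply(segs, function(s) cbind(s$vertices, s$segment_id)))
  d <- as.matrix(stats::dist(V[, 1:3])); diag(d) <- Inf
  d[outer(V[, 4], V[, 4], "==")] <- Inf
  g <- igraph::graph_from_adjacency_matrix(d <= eps_um, mode = "undirected")
  comp <- igraph::components(g)$membership
  grps <- split(seq_along(comp), comp)
  keep <- vapply(grps, function(m) length(m) >= 2 && length(unique(V[m, 4])) >= 2,
                 logical(1))
  sort(unname(vapply(grps[keep], function(m) paste(sort(m), collapse = ","),
                     character(1))))
}

## Canonical node strings from a linked network, comparable to the oracle.
network_node_strings <- function(net, segs) {
  if (!nrow(net$members)) return(character(0))
  offs <- cumsum(c(0, vapply(segs, function(s) nrow(s$vertices), 0L)))
  sort(unname(vapply(split(seq_len(nrow(net$members)), net$members$node_id),
                     function(i) paste(sort(offs[net$members$segment_id[i]] +
                                              net$members$vertex_index[i]),
                                       collapse = ","), character(1))))
}

## Random polyline segment generator for property tests.
random_segment <- function(id, n = NULL, span = 10) {
  n <- n %||% sample(2:6, 1)
  p0 <- stats::runif(2, 0, span)
  filament_segment(id, cbind(p0[1] + cumsum(stats::runif(n, 0.3, 1)),
                             p0[2] + cumsum(stats::runif(n, 0.3, 1)),
                             stats::runif(n, 0, 0.5)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
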