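#' Filament segment
#'
#' One extracted keratin filament (or bundle): an ordered polygonal chain of
#' 3D vertices in micrometers, the field's standard representation of
#' centerline extraction output.
#'
#' @param segment_id integer id.
#' @param vertices numeric `n x 3` matrix (x, y, z in micrometers), `n >= 2`,
#'   consecutive vertices distinct, no NaN.
#' @param mean_intensity mean image intensity along the chain (a.u.).
#' @return object of class `filament_segment`.
#' @export
filament_segment <- function(segment_id, vertices, mean_intensity = NA_real_) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) == 2) vertices <- cbind(vertices, 0)
  if (ncol(vertices) != 3) stopf("vertices must be n x 3")
  if (nrow(vertices) < 2) stopf("a segment needs at least 2 vertices")
  if (anyNA(vertices) || any(!is.finite(vertices)))
    stopf("vertex coordinates must be finite")
  d <- sqrt(rowSums((vertices[-1, , drop = FALSE] -
                       vertices[-nrow(vertices), , drop = FALSE])^2))
  if (any(d == 0)) stopf("consecutive vertices must be distinct")
  structure(list(segment_id = as.integer(segment_id), vertices = vertices,
                 mean_intensity = mean_intensity),
            class = "filament_segment")
}

#' @export
print.filament_segment <- function(x, ...) {
  cat(sprintf("<filament_segment> #%d, %d vertices, chord %.2f um, arc %.2f um\n",
              x$segment_id, nrow(x$vertices), segment_length(x),
              segment_arclength(x)))
  invisible(x)
}

#' Segment length (chord) and arc length
#'
#' Segment length follows the convention used for keratin network analysis:
#' the straight-line (Euclidean) distance between the two end vertices of the
#' chain — not the contour length. `segment_arclength` gives the contour
#' (summed vertex-to-vertex) length; chord <= arc always.
#'
#' @param segment a [filament_segment()].
#' @return length in micrometers.
#' @export
segment_length <- function(segment) {
  V <- segment$vertices
  sqrt(sum((V[nrow(V), ] - V[1, ])^2))
}

#' @rdname segment_length
#' @export
segment_arclength <- function(segment) polyline_arclength(segment$vertices)

#' Mean segment curvature
#'
#' Classical curvature along the chain: the polyline is resampled at uniform
#' arc spacing `resample_ds_um`, the coordinates are Gaussian-smoothed along
#' the arc, and the magnitude of the second derivative of position with
#' respect to arc length (equal to the derivative of the unit tangent) is
#' averaged over interior samples. Samples within the smoothing support of
#' either end are excluded to avoid boundary bias.
#'
#' By default the smoothing scale is coupled to the resampling step
#' (`smooth_sigma_um = 2 * resample_ds_um`), which keeps the estimator's
#' total error of order `ds^2`: halving the step at least halves the error
#' on smooth curves.
#'
#' @param segment a [filament_segment()] (or bare vertex matrix).
#' @param resample_ds_um uniform resampling step, micrometers.
#' @param smooth_sigma_um Gaussian smoothing sigma along the arc,
#'   micrometers; `NULL` (default) uses `2 * resample_ds_um`.
#' @return mean curvature in 1/um; `NaN` with attribute `reason` when the
#'   chain is too short to estimate.
#' @export
segment_curvature <- function(segment, resample_ds_um = 0.25,
                              smooth_sigma_um = NULL) {
  V <- if (inherits(segment, "filament_segment")) segment$vertices
       else as.matrix(segment)
  ds <- resample_ds_um
  check_positive(ds, "resample_ds_um")
  sigma <- smooth_sigma_um %||% (2 * ds)
  P <- resample_polyline(V, ds)
  if (nrow(P) < 5)
    return(structure(NaN, reason = "fewer than 5 samples after resampling"))
  ## actual uniform spacing after resampling (nearest integer subdivision)
  ds <- polyline_arclength(P) / (nrow(P) - 1)
  sig_s <- sigma / ds
  if (sig_s > 0) {
    k <- gauss_kernel(sig_s)
    P <- sep_filter(P, k, 1)
  }
  n <- nrow(P)
  d2 <- (P[-c(1, 2), , drop = FALSE] - 2 * P[-c(1, n), , drop = FALSE] +
           P[-c(n - 1, n), , drop = FALSE]) / ds^2
  kappa <- sqrt(rowSums(d2^2))       # at samples 2..n-1
  margin <- ceiling(4 * sig_s) + 1
  lo <- margin; hi <- length(kappa) - margin + 1
  if (hi < lo)
    return(structure(NaN, reason = "segment shorter than smoothing support"))
  mean(kappa[lo:hi])
}

#' Link segments into a connected network via junction nodes
#'
#' Clusters vertices of *different* segments that lie within a proximity
#' radius into junction nodes (single-linkage: clusters are the connected
#' components of the within-epsilon graph). Clusters containing at least two
#' vertices from at least two distinct segments become nodes; the node
#' position is the centroid of its member vertices. Deterministic under
#' input reordering.
#'
#' @param segments list of [filament_segment()].
#' @param epsilon_px linking radius in pixels (default 2, matching the snake
#'   point spacing).
#' @param pixel_size_um conversion from the segment coordinates (um) to px.
#' @return object of class `filament_network`: `segments`, `nodes` (data
#'   frame: node_id, x/y/z_um, degree), `members` (data frame: node_id,
#'   segment_id, vertex_index), `adjacency` (data frame of segment pairs
#'   sharing a node).
#' @export
link_nodes <- function(segments, epsilon_px = 2, pixel_size_um = 0.23) {
  check_positive(epsilon_px, "epsilon_px")
  eps_um <- epsilon_px * pixel_size_um
  ids <- vapply(segments, `[[`, 0L, "segment_id")
  if (anyDuplicated(ids)) stopf("segment ids must be unique")
  V <- do.call(rbind, lapply(segments, function(s)
    cbind(s$vertices, s$segment_id, seq_len(nrow(s$vertices)))))
  nodes <- data.frame(node_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), z_um = numeric(0), degree = integer(0))
  members <- data.frame(node_id = integer(0), segment_id = integer(0),
                        vertex_index = integer(0))
  adjacency <- data.frame(segment_a = integer(0), segment_b = integer(0),
                          node_id = integer(0))
  if (!is.null(V) && nrow(V) > 1) {
    P <- V[, 1:3, drop = FALSE]
    seg <- V[, 4]
    ## cell-list neighbor search at radius eps
    cell <- floor(P[, 1:2] / eps_um)
    key <- paste(cell[, 1], cell[, 2])
    buckets <- split(seq_len(nrow(P)), key)
    pairs_i <- integer(0); pairs_j <- integer(0)
    cell_xy <- unique(cell)
    lookup <- function(cx, cy) buckets[[paste(cx, cy)]]
    for (b in seq_len(nrow(cell_xy))) {
      cx <- cell_xy[b, 1]; cy <- cell_xy[b, 2]
      here <- lookup(cx, cy)
      neigh <- unlist(lapply(-1:1, function(dx) lapply(-1:1, function(dy)
        lookup(cx + dx, cy + dy))), use.names = FALSE)
      neigh <- neigh[neigh >= min(here)]
      for (i in here) {
        cand <- neigh[neigh > i & seg[neigh] != seg[i]]
        if (!length(cand)) next
        d2 <- (P[cand, 1] - P[i, 1])^2 + (P[cand, 2] - P[i, 2])^2 +
          (P[cand, 3] - P[i, 3])^2
        hit <- cand[d2 <= eps_um^2]
        pairs_i <- c(pairs_i, rep(i, length(hit)))
        pairs_j <- c(pairs_j, hit)
      }
    }
    if (length(pairs_i)) {
      gr <- igraph::graph_from_edgelist(cbind(pairs_i, pairs_j), directed = FALSE)
      gr <- igraph::add_vertices(gr, max(0, nrow(P) - igraph::vcount(gr)))
      comp <- igraph::components(gr)$membership
      keep <- which(tabulate(comp) >= 2)
      node_list <- list()
      for (cl in keep) {
        mem <- which(comp == cl)
        if (length(unique(seg[mem])) < 2) next
        node_list[[length(node_list) + 1]] <- mem
      }
      if (length(node_list)) {
        ## stable ordering: sort nodes by centroid (y, x, z)
        cent <- t(vapply(node_list, function(m) colMeans(P[m, , drop = FALSE]),
                         numeric(3)))
        ord <- order(cent[, 2], cent[, 1], cent[, 3])
        node_list <- node_list[ord]; cent <- cent[ord, , drop = FALSE]
        nodes <- data.frame(node_id = seq_along(node_list),
                            x_um = cent[, 1], y_um = cent[, 2], z_um = cent[, 3],
                            degree = vapply(node_list, function(m)
                              length(unique(seg[m])), 0L))
        members <- do.call(rbind, lapply(seq_along(node_list), function(k) {
          m <- node_list[[k]]
          data.frame(node_id = k, segment_id = as.integer(seg[m]),
                     vertex_index = as.integer(V[m, 5]))
        }))
        adjacency <- do.call(rbind, lapply(seq_along(node_list), function(k) {
          sids <- sort(unique(members$segment_id[members$node_id == k]))
          if (length(sids) < 2) return(NULL)
          cmb <- utils::combn(sids, 2)
          data.frame(segment_a = cmb[1, ], segment_b = cmb[2, ], node_id = k)
        }))
        adjacency <- adjacency %||% data.frame(segment_a = integer(0),
                                               segment_b = integer(0),
                                               node_id = integer(0))
      }
    }
  }
  structure(list(segments = segments, nodes = nodes, members = members,
                 adjacency = adjacency, epsilon_px = epsilon_px,
                 pixel_size_um = pixel_size_um),
            class = "filament_network")
}

#' @export
print.filament_network <- function(x, ...) {
  cat(sprintf("<filament_network> %d segments, %d nodes (epsilon %.3g px)\n",
              length(x$segments), nrow(x$nodes), x$epsilon_px))
  invisible(x)
}

#' Segment orientation vectors
#'
#' Translates each segment into its end-to-end chord vector projected on the
#' xy plane (last minus first vertex, in extraction order). In `axial` mode
#' angles are mapped to [0, 180) degrees, the natural convention for apolar
#' filaments; `as_traced` (default) keeps the signed chord so that sum
#' vectors retain a direction.
#'
#' @param network a `filament_network` or a list of [filament_segment()].
#' @param polarity `"as_traced"` or `"axial"`.
#' @return data frame: `segment_id`, `vx_um`, `vy_um`, `magnitude_um`,
#'   `angle_deg`.
#' @export
segment_orientation_vectors <- function(network, polarity = c("as_traced", "axial")) {
  polarity <- match.arg(polarity)
  segments <- if (inherits(network, "filament_network")) network$segments else network
  if (!length(segments))
    return(data.frame(segment_id = integer(0), vx_um = numeric(0),
                      vy_um = numeric(0), magnitude_um = numeric(0),
                      angle_deg = numeric(0)))
  out <- do.call(rbind, lapply(segments, function(s) {
    V <- s$vertices
    v <- V[nrow(V), 1:2] - V[1, 1:2]
    data.frame(segment_id = s$segment_id, vx_um = v[1], vy_um = v[2])
  }))
  out$magnitude_um <- sqrt(out$vx_um^2 + out$vy_um^2)
  ang <- atan2(out$vy_um, out$vx_um) * 180 / pi
  ang <- ang %% 360
  if (polarity == "axial") ang <- ang %% 180
  out$angle_deg <- ang
  out
}

#' Magnitude-weighted radial histogram and sum vector
#'
#' Bins a set of 2D vectors by angle, weighting each by its magnitude, and
#' returns the component-wise sum vector summarizing net orientation. The
#' histogram total equals the summed magnitudes; an empty input gives a zero
#' histogram and zero sum vector.
#'
#' @param vectors two-column matrix (vx, vy) or the data frame returned by
#'   [segment_orientation_vectors()].
#' @param n_bins number of angular bins (>= 4); default 24 bins of 15 deg.
#' @return list: `bin_start_deg`, `weight`, `sum_vector` (c(x, y)),
#'   `sum_magnitude`, `sum_angle_deg`.
#' @export
radial_histogram <- function(vectors, n_bins = 24L) {
  if (n_bins < 4) stopf("n_bins must be >= 4")
  if (is.data.frame(vectors)) vectors <- cbind(vectors$vx_um, vectors$vy_um)
  vectors <- matrix(as.numeric(vectors), ncol = 2)
  bin_start <- seq(0, 360, length.out = n_bins + 1)[-(n_bins + 1)]
  if (!nrow(vectors))
    return(list(bin_start_deg = bin_start, weight = numeric(n_bins),
                sum_vector = c(0, 0), sum_magnitude = 0, sum_angle_deg = NA_real_))
  mag <- sqrt(rowSums(vectors^2))
  ang <- (atan2(vectors[, 2], vectors[, 1]) * 180 / pi) %% 360
  bin <- pmin(floor(ang / (360 / n_bins)), n_bins - 1) + 1
  wt <- vapply(seq_len(n_bins), function(b) sum(mag[bin == b]), 0)
  sv <- colSums(vectors)
  list(bin_start_deg = bin_start, weight = wt, sum_vector = sv,
       sum_magnitude = sqrt(sum(sv^2)),
       sum_angle_deg = (atan2(sv[2], sv[1]) * 180 / pi) %% 360)
}

#' Per-segment statistics table
#'
#' @param segments list of [filament_segment()] (or a `filament_network`).
#' @param resample_ds_um,smooth_sigma_um curvature estimator settings, see
#'   [segment_curvature()].
#' @return data frame with one row per segment: id, vertex count, chord
#'   length, arc length, mean curvature, orientation vector and angle.
#' @export
segment_stats <- function(segments, resample_ds_um = 0.25,
                          smooth_sigma_um = NULL) {
  if (inherits(segments, "filament_network")) segments <- segments$segments
  ori <- segment_orientation_vectors(segments)
  if (!length(segments))
    return(cbind(data.frame(n_vertices = integer(0), length_um = numeric(0),
                            arc_length_um = numeric(0),
                            curvature_per_um = numeric(0)), ori))
  base <- data.frame(
    segment_id = vapply(segments, `[[`, 0L, "segment_id"),
    n_vertices = vapply(segments, function(s) nrow(s$vertices), 0L),
    length_um = vapply(segments, segment_length, 0),
    arc_length_um = vapply(segments, segment_arclength, 0),
    curvature_per_um = vapply(segments, function(s)
      as.numeric(segment_curvature(s, resample_ds_um, smooth_sigma_um)), 0),
    mean_intensity = vapply(segments, function(s)
      as.numeric(s$mean_intensity %||% NA_real_), 0))
  merge(base, ori, by = "segment_id", sort = TRUE)
}

#' Partition a network by cell territories
#'
#' Assigns each segment to the cell mask containing the majority of its
#' vertices (xy projection); segments with no vertex in any mask are
#' reported separately. Masks must be disjoint.
#'
#' @param network a `filament_network` or list of segments.
#' @param cell_masks list of logical matrices (image frame, `[y, x]`).
#' @param pixel_size_um conversion from vertex um coordinates to pixels.
#' @return list: `per_cell` (list of segment lists), `stats` (list of
#'   [segment_stats()] tables), `unassigned` (segment list).
#' @export
per_cell_partition <- function(network, cell_masks, pixel_size_um = 0.23) {
  segments <- if (inherits(network, "filament_network")) network$segments else network
  if (length(cell_masks) > 1) {
    tot <- Reduce(`+`, lapply(cell_masks, function(m) m * 1L))
    if (any(tot > 1)) stopf("cell masks overlap")
  }
  assign_one <- function(s) {
    xp <- round(s$vertices[, 1] / pixel_size_um) + 1L
    yp <- round(s$vertices[, 2] / pixel_size_um) + 1L
    counts <- vapply(cell_masks, function(m) {
      ok <- xp >= 1 & xp <= ncol(m) & yp >= 1 & yp <= nrow(m)
      sum(m[cbind(yp[ok], xp[ok])])
    }, 0L)
    if (all(counts == 0)) 0L else which.max(counts)
  }
  lab <- vapply(segments, assign_one, 0L)
  per_cell <- lapply(seq_along(cell_masks), function(i) segments[lab == i])
  list(per_cell = per_cell,
       stats = lapply(per_cell, segment_stats),
       unassigned = segments[lab == 0L])
}

#' Mann-Whitney U comparison of two samples
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test, the standard choice for
#' the typically non-Gaussian segment-property distributions. Exact
#' enumeration is used for small untied samples (both n <= 8); otherwise the
#' normal approximation with tie correction.
#'
#' @param sample_a,sample_b nonempty numeric vectors.
#' @return list: `U` (statistic for `sample_a`), `p_value`, `method`.
#' @export
compare_groups <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stopf("both samples must be nonempty")
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  exact <- length(sample_a) <= 8 && length(sample_b) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                            exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}
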