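## Centerline extraction: Hessian ridge enhancement, non-maximum suppression,
## morphological thinning and graph-based polyline tracing. Provides the same
## contract as external snake-based extraction tools (image in, polylines
## out) without re-implementing their active-contour optimization; a reader
## for snake text files covers interop with real TSOAX output.

#' Multiscale Hessian ridge enhancement
#'
#' Computes, plane by plane, the eigenvalues of the Gaussian-scale Hessian
#' and keeps the scale-normalized magnitude of the most negative eigenvalue
#' (bright curvilinear structures on dark background), maximized over
#' scales. The response is normalized to [0, 1] over the stack; the ridge
#' normal direction (eigenvector of the principal eigenvalue at the best
#' scale) is retained for non-maximum suppression.
#'
#' @param stack an [image_stack] or a matrix.
#' @param scales_px Gaussian scales (sigma, px); choose around the expected
#'   filament half-width.
#' @return object of class `ridge_response`: `response` array `(z, y, x)` in
#'   [0, 1], `normal_x`/`normal_y` arrays, and the source metadata.
#' @export
ridge_enhance <- function(stack, scales_px = c(1.2, 2)) {
  if (is.matrix(stack)) stack <- image_stack(stack)
  if (!length(scales_px) || any(scales_px <= 0)) stopf("need positive scales")
  v <- stack$voxels
  if (length(dim(v)) == 4L) stopf("ridge_enhance expects a single time point")
  nz <- dim(v)[1]; ny <- dim(v)[2]; nx <- dim(v)[3]
  resp <- array(0, dim(v)); nxv <- array(0, dim(v)); nyv <- array(0, dim(v))
  for (z in seq_len(nz)) {
    m <- v[z, , ]
    best <- matrix(0, ny, nx); bx <- matrix(0, ny, nx); by <- matrix(0, ny, nx)
    for (s in scales_px) {
      g0 <- gauss_kernel(s); g1 <- gauss_kernel(s, 1L); g2 <- gauss_kernel(s, 2L)
      Ixx <- sep_filter(m, g0, g2)
      Iyy <- sep_filter(m, g2, g0)
      Ixy <- sep_filter(m, g1, g1)
      tr <- Ixx + Iyy
      dsc <- sqrt(pmax((Ixx - Iyy)^2 + 4 * Ixy^2, 0))
      lam <- (tr - dsc) / 2                  # most negative eigenvalue
      r <- s^2 * pmax(-lam, 0)               # scale-normalized ridge strength
      upd <- r > best
      if (any(upd)) {
        ## eigenvector for lam: (Ixy, lam - Ixx), normalized; ridge normal
        ex <- Ixy; ey <- lam - Ixx
        nrm <- sqrt(ex^2 + ey^2)
        flat <- nrm < 1e-12
        ex <- ifelse(flat, 1, ex / pmax(nrm, 1e-12))
        ey <- ifelse(flat, 0, ey / pmax(nrm, 1e-12))
        best[upd] <- r[upd]; bx[upd] <- ex[upd]; by[upd] <- ey[upd]
      }
    }
    resp[z, , ] <- best; nxv[z, , ] <- bx; nyv[z, , ] <- by
  }
  ## normalize to [0, 1]; responses at numerical-noise level (e.g. constant
  ## images, where the Hessian is zero up to rounding) are treated as zero
  mx <- max(resp)
  if (mx > 1e-9 * max(abs(v), 1)) resp <- resp / mx else resp[] <- 0
  structure(list(response = resp, normal_x = nxv, normal_y = nyv,
                 scales_px = scales_px, pixel_size_um = stack$pixel_size_um,
                 z_step_um = stack$z_step_um),
            class = "ridge_response")
}

#' @export
print.ridge_response <- function(x, ...) {
  cat(sprintf("<ridge_response> %s, scales %s px\n",
              paste(dim(x$response), collapse = " x "),
              paste(x$scales_px, collapse = ", ")))
  invisible(x)
}

## Zhang-Suen thinning of a logical matrix, vectorized over pixels.
thin_binary <- function(B) {
  B <- B * 1L
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- shift_mat(B, 1, 0);  p3 <- shift_mat(B, 1, -1)
      p4 <- shift_mat(B, 0, -1); p5 <- shift_mat(B, -1, -1)
      p6 <- shift_mat(B, -1, 0); p7 <- shift_mat(B, -1, 1)
      p8 <- shift_mat(B, 0, 1);  p9 <- shift_mat(B, 1, 1)
      ## p2 = north neighbor (row above in matrix = y-1): use shift down
      ## ordering: p2 N, p3 NE, p4 E, p5 SE, p6 S, p7 SW, p8 W, p9 NW
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- cbind(as.vector(p2), as.vector(p3), as.vector(p4),
                    as.vector(p5), as.vector(p6), as.vector(p7),
                    as.vector(p8), as.vector(p9))
      trans <- rowSums((seqs == 0) * (cbind(seqs[, -1], seqs[, 1]) == 1))
      A <- matrix(trans, nrow(B), ncol(B))
      if (phase == 1) {
        cond <- B == 1 & bsum >= 2 & bsum <= 6 & A == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- B == 1 & bsum >= 2 & bsum <= 6 & A == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) { B[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  B == 1L
}

## Interpolated ridge response one unit along the per-pixel normal direction.
offset_response <- function(R, NX, NY, sign) {
  ax <- sign * NX; ay <- sign * NY
  sx <- ifelse(ax >= 0, 1, -1); sy <- ifelse(ay >= 0, 1, -1)
  fx <- abs(ax); fy <- abs(ay)
  pick <- function(dy, dx) {
    pos <- shift_mat(R, dy, dx)   # value at (y - dy, x - dx)
    pos
  }
  ## value at (y + ay, x + ax): gather from shifted matrices
  Rx0y0 <- R
  Rx1y0 <- ifelse(sx > 0, pick(0, -1), pick(0, 1))
  Rx0y1 <- ifelse(sy > 0, pick(-1, 0), pick(1, 0))
  Rx1y1 <- ifelse(sx > 0,
                  ifelse(sy > 0, pick(-1, -1), pick(1, -1)),
                  ifelse(sy > 0, pick(-1, 1), pick(1, 1)))
  (1 - fx) * (1 - fy) * Rx0y0 + fx * (1 - fy) * Rx1y0 +
    (1 - fx) * fy * Rx0y1 + fx * fy * Rx1y1
}

#' Extract filament centerlines as polylines
#'
#' Thresholds the normalized ridge response at `tau`, keeps only pixels that
#' are local maxima along the ridge normal (non-maximum suppression), thins
#' the result to a one-pixel skeleton, splits it at branch points, prunes
#' short pieces, and resamples each path at `spacing_px`. Operates on the
#' maximum projection of the response; each vertex receives a z coordinate
#' from the response-weighted centroid along z at its position. Default
#' `tau = 0.008` and `spacing_px = 2` follow the parameterization used for
#' keratin networks in snake-based extraction.
#'
#' @param ridge a `ridge_response` from [ridge_enhance()] (or a stack /
#'   matrix, which is ridge-enhanced first with default scales).
#' @param tau ridge threshold on the normalized response, in (0, 1).
#' @param spacing_px vertex spacing of the output polylines, px (>= 1).
#' @param min_length_px minimum traced path length, px.
#' @param intensity_stack optional [image_stack] used for per-segment mean
#'   intensity (defaults to the ridge response).
#' @param validation_k hysteresis validation: a traced path is kept only if
#'   its peak response exceeds `median + validation_k * mad` of the response
#'   image (a robust ceiling of the noise ridge floor). `tau` remains the
#'   lower threshold defining ridge extent; set `validation_k = 0` to
#'   disable.
#' @return list of [filament_segment()] with coordinates in micrometers.
#' @export
extract_centerlines <- function(ridge, tau = 0.008, spacing_px = 2,
                                min_length_px = 10, intensity_stack = NULL,
                                validation_k = 8) {
  if (!inherits(ridge, "ridge_response")) ridge <- ridge_enhance(ridge)
  if (tau <= 0 || tau >= 1) stopf("tau must lie in (0, 1)")
  if (spacing_px < 1) stopf("spacing_px must be >= 1")
  nz <- dim(ridge$response)[1]
  ny <- dim(ridge$response)[2]; nx <- dim(ridge$response)[3]
  ## composite response + per-pixel best plane
  if (nz > 1) {
    R <- apply(ridge$response, c(2, 3), max)
    zbest <- apply(ridge$response, c(2, 3), which.max)
    NX <- matrix(0, ny, nx); NY <- matrix(0, ny, nx)
    for (z in seq_len(nz)) {
      sel <- zbest == z
      NX[sel] <- ridge$normal_x[z, , ][sel]
      NY[sel] <- ridge$normal_y[z, , ][sel]
    }
  } else {
    R <- ridge$response[1, , ]
    NX <- ridge$normal_x[1, , ]; NY <- ridge$normal_y[1, , ]
  }
  ## robust noise floor of the response; tau thresholds the floor-subtracted,
  ## renormalized response (identical to thresholding R on clean images,
  ## where the floor is ~0, but bounds ridge extent under noise)
  floor_val <- stats::median(R) + 3 * stats::mad(R)
  Rn <- pmax((R - floor_val) / max(1 - floor_val, 1e-12), 0)
  fg <- Rn >= tau
  if (!any(fg)) return(list())
  nms <- R >= offset_response(R, NX, NY, 1) - 1e-12 &
    R >= offset_response(R, NX, NY, -1) - 1e-12
  B <- fg & nms
  B[c(1, ny), ] <- FALSE; B[, c(1, nx)] <- FALSE
  skel <- thin_binary(B)
  paths <- trace_skeleton(skel)
  psz <- ridge$pixel_size_um
  zstep <- ridge$z_step_um
  int_src <- if (!is.null(intensity_stack)) intensity_stack$voxels else ridge$response
  high_thresh <- if (validation_k > 0)
    stats::median(R) + validation_k * stats::mad(R) else 0
  segs <- list()
  for (p in paths) {
    if (nrow(p) < 2) next
    if (polyline_arclength(p) < min_length_px) next
    r_path <- R[cbind(p[, 2] + 1, p[, 1] + 1)]
    peak <- max(r_path)
    if (peak < max(tau, high_thresh)) next
    ## trim low-response tails: the ridge response of a filament halves at
    ## its tip and decays beyond, so ends below 40% of the path median are
    ## overshoot past the true endpoint
    med_r <- stats::median(r_path)
    keep_lo <- 1L; keep_hi <- nrow(p)
    while (keep_lo < keep_hi && r_path[keep_lo] < 0.4 * med_r) keep_lo <- keep_lo + 1L
    while (keep_hi > keep_lo && r_path[keep_hi] < 0.4 * med_r) keep_hi <- keep_hi - 1L
    p <- p[keep_lo:keep_hi, , drop = FALSE]
    if (nrow(p) < 2 || polyline_arclength(p) < min_length_px) next
    P <- resample_polyline(p, spacing_px)
    if (nrow(P) < 2) next
    ## z from response-weighted centroid along the stack at each vertex
    xi <- pmin(pmax(round(P[, 1]), 0), nx - 1) + 1
    yi <- pmin(pmax(round(P[, 2]), 0), ny - 1) + 1
    zc <- numeric(nrow(P)); inten <- numeric(nrow(P))
    for (i in seq_len(nrow(P))) {
      col <- if (length(dim(int_src)) == 3) int_src[, yi[i], xi[i]] else
        int_src[yi[i], xi[i]]
      if (nz > 1) {
        rcol <- ridge$response[, yi[i], xi[i]]
        wsum <- sum(rcol)
        zc[i] <- if (wsum > 0) sum(rcol * (seq_len(nz) - 1)) / wsum else (nz - 1) / 2
      }
      inten[i] <- max(col)
    }
    segs[[length(segs) + 1]] <- filament_segment(
      length(segs) + 1L,
      cbind(P[, 1] * psz, P[, 2] * psz, zc * zstep),
      mean_intensity = mean(inten))
  }
  segs
}

## Split a 1-px skeleton into simple paths between endpoints/branch points.
## Returns list of n x 2 matrices of 0-based (x, y) pixel coordinates.
trace_skeleton <- function(skel) {
  pix <- which(skel, arr.ind = TRUE)       # [row=y, col=x], 1-based
  if (!nrow(pix)) return(list())
  ny <- nrow(skel); nx <- ncol(skel)
  id <- matrix(0L, ny, nx)
  id[pix] <- seq_len(nrow(pix))
  ## 8-neighbor edges; drop a diagonal edge when an orthogonal 2-step path
  ## exists through a common neighbor (avoids spurious triangles)
  edges <- NULL
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (o in offs) {
    dy <- o[1]; dx <- o[2]
    y2 <- pix[, 1] + dy; x2 <- pix[, 2] + dx
    ok <- y2 >= 1 & y2 <= ny & x2 >= 1 & x2 <= nx
    ok[ok] <- skel[cbind(y2[ok], x2[ok])]
    if (!any(ok)) next
    a <- id[pix[ok, , drop = FALSE]]
    b <- id[cbind(y2[ok], x2[ok])]
    if (dy != 0 && dx != 0) {
      ## diagonal: skip if both share an orthogonal neighbor
      y1 <- pix[ok, 1]; x1 <- pix[ok, 2]
      via1 <- skel[cbind(y1, x2[ok])]
      via2 <- skel[cbind(y2[ok], x1)]
      keep <- !(via1 | via2)
      a <- a[keep]; b <- b[keep]
    }
    if (length(a)) edges <- rbind(edges, cbind(a, b))
  }
  n <- nrow(pix)
  if (is.null(edges)) {
    return(list())
  }
  gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(gr) < n) gr <- igraph::add_vertices(gr, n - igraph::vcount(gr))
  deg <- igraph::degree(gr)
  branch <- which(deg >= 3)
  ## remove branch vertices; remaining components are simple paths
  gr2 <- igraph::delete_vertices(gr, branch)
  keepv <- setdiff(seq_len(n), branch)
  comp <- igraph::components(gr2)
  paths <- list()
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)       # indices within gr2
    orig <- keepv[vs]
    if (length(vs) == 1) { paths[[length(paths) + 1]] <- orig; next }
    sub <- igraph::induced_subgraph(gr2, vs)
    dsub <- igraph::degree(sub)
    ends <- which(dsub <= 1)
    if (length(ends) >= 2) {
      sp <- igraph::shortest_paths(sub, from = ends[1], to = ends[2])$vpath[[1]]
    } else {
      ## cycle: walk it from an arbitrary vertex
      sp <- igraph::dfs(sub, root = 1, order = TRUE)$order
    }
    paths[[length(paths) + 1]] <- orig[as.integer(sp)]
  }
  ## re-attach one adjacent branch pixel at each open end so segments meet
  adj <- igraph::as_adj_list(gr)
  out <- list()
  for (p in paths) {
    if (length(p) >= 1) {
      first <- p[1]; last <- p[length(p)]
      nb_first <- setdiff(as.integer(adj[[first]]), p)
      nb_first <- nb_first[nb_first %in% branch]
      nb_last <- setdiff(as.integer(adj[[last]]), p)
      nb_last <- nb_last[nb_last %in% branch]
      if (length(nb_first)) p <- c(nb_first[1], p)
      if (length(nb_last)) p <- c(p, nb_last[1])
    }
    if (length(p) >= 2)
      out[[length(out) + 1]] <- cbind(pix[p, 2] - 1, pix[p, 1] - 1)  # (x, y)
  }
  out
}

#' Read snake text files (TSOAX interop)
#'
#' Parses the plain-text snake dialect documented in the package fixture:
#' comment lines start with `#`; each snake block is introduced by a header
#' line `snake <id>`; vertex rows carry five numeric fields
#' `index x y z intensity` (coordinates in pixels); an optional trailing
#' section introduced by `junctions` lists `x y z` rows. Pixel coordinates
#' are converted to micrometers.
#'
#' @param path file path.
#' @param pixel_size_um,z_step_um voxel calibration for px to um conversion.
#' @return list of [filament_segment()]; junctions (if present) in
#'   attribute `junctions_um`.
#' @export
read_tsoax_snakes <- function(path, pixel_size_um = 0.23, z_step_um = 0.5) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  segs <- list()
  cur <- NULL; cur_id <- NA_integer_; cur_int <- numeric(0)
  junctions <- NULL
  in_junctions <- FALSE
  flush <- function() {
    if (!is.null(cur) && nrow(cur) >= 2) {
      segs[[length(segs) + 1]] <<- filament_segment(
        cur_id, cbind(cur[, 1] * pixel_size_um, cur[, 2] * pixel_size_um,
                      cur[, 3] * z_step_um),
        mean_intensity = mean(cur_int))
    }
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    if (grepl("^snake\\s+\\d+$", ln, ignore.case = TRUE)) {
      flush()
      cur <- matrix(numeric(0), 0, 3); cur_int <- numeric(0)
      cur_id <- as.integer(sub("^snake\\s+", "", tolower(ln)))
      in_junctions <- FALSE
      next
    }
    if (grepl("^junctions$", ln, ignore.case = TRUE)) {
      flush(); cur <- NULL
      in_junctions <- TRUE
      next
    }
    fields <- strsplit(ln, "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (in_junctions) {
      if (length(vals) != 3 || anyNA(vals))
        stopf("malformed junction line %d in %s: '%s'", i, path, lines[i])
      junctions <- rbind(junctions, vals * c(pixel_size_um, pixel_size_um, z_step_um))
      next
    }
    if (is.null(cur))
      stopf("line %d in %s: vertex row before any 'snake' header", i, path)
    if (length(vals) != 5 || anyNA(vals))
      stopf("malformed vertex line %d in %s: '%s'", i, path, lines[i])
    cur <- rbind(cur, vals[2:4])
    cur_int <- c(cur_int, vals[5])
  }
  flush()
  if (!is.null(junctions)) attr(segs, "junctions_um") <- junctions
  segs
}

#' Centerline recovery against ground truth
#'
#' Bidirectional matched-distance score: the fraction of ground-truth arc
#' length lying within `tol_px` of any extracted polyline (recall) and the
#' fraction of extracted arc length within `tol_px` of the truth
#' (precision), both measured on dense resamplings in the xy plane.
#'
#' @param truth_curves list of ground-truth curves (n x 2/3 matrices, um).
#' @param segments extracted [filament_segment()] list (um coordinates).
#' @param pixel_size_um converts um to px for the tolerance.
#' @param tol_px matching tolerance in pixels.
#' @return list: `recall`, `precision`, `f1`.
#' @export
centerline_recovery <- function(truth_curves, segments, pixel_size_um = 0.23,
                                tol_px = 1.5) {
  tol <- tol_px
  to_px <- function(P) cbind(P[, 1], P[, 2]) / pixel_size_um
  tr <- lapply(truth_curves, function(P) resample_polyline(to_px(P), 0.5))
  ex <- lapply(segments, function(s) resample_polyline(to_px(s$vertices), 0.5))
  if (!length(ex)) return(list(recall = 0, precision = NA_real_, f1 = 0))
  frac_matched <- function(src, ref) {
    pts <- do.call(rbind, src)
    d <- rep(Inf, nrow(pts))
    for (rp in ref) d <- pmin(d, dist_to_polyline(pts, rp))
    mean(d <= tol)
  }
  recall <- frac_matched(tr, ex)
  precision <- frac_matched(ex, tr)
  f1 <- if (recall + precision > 0) 2 * recall * precision / (recall + precision) else 0
  list(recall = recall, precision = precision, f1 = f1)
}
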