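#' Run configuration
#'
#' Central parameter bundle for reproducible pipeline runs. Every physical
#' parameter must be positive; the resolved configuration (with the seed) is
#' written beside every output bundle so any run can be reproduced exactly.
#'
#' @param ... overrides of the defaults listed below.
#' @return list of class `run_config`.
#' @details Defaults: pixel_size_um 0.23, z_step_um 0.5, dt_min 1,
#'   substrate E 11000 Pa / nu 0.5, extraction tau 0.008 / spacing 2 px /
#'   min_length 10 px, linking epsilon 2 px, PIV window 32 px / overlap 0.5,
#'   lambda 1e-4, pattern disc 47 um, seed 1.
#' @export
run_config <- function(...) {
  cfg <- list(
    pixel_size_um = 0.23, z_step_um = 0.5, dt_min = 1,
    substrate = list(E_pa = 11000, nu = 0.5),
    extraction = list(tau = 0.008, spacing_px = 2, min_length_px = 10,
                      scales_px = c(1.2, 2)),
    linking_epsilon_px = 2,
    piv = list(window_px = 32L, overlap = 0.5),
    lambda = 1e-4,
    pattern = list(shape = "disc", diameter_um = 47,
                   image_shape = c(256L, 256L)),
    flow = list(speed_um_min = 0.3, n_frames = 5, mode = "uniform"),
    rotation = list(omega_deg_per_frame = 2, n_frames = 5, dt_min = 3),
    ablation = list(n_cells = 4, cell = 1, traction_scale = 0.8),
    n_curves = 40,
    seed = 1L)
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      utils::modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  for (nm in c("pixel_size_um", "z_step_um", "dt_min", "lambda"))
    if (cfg[[nm]] < 0 || (nm != "lambda" && cfg[[nm]] <= 0))
      stopf("config field '%s' must be positive", nm)
  structure(cfg, class = c("run_config", "list"))
}

#' Read / write a run configuration (JSON or YAML by extension)
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @param config a [run_config()].
#' @return `read_config` returns a [run_config()].
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else stopf("unsupported config format: .%s", ext)
  do.call(run_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  plain <- unclass(config)
  if (ext == "json")
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("writing YAML configs requires the 'yaml' package")
    yaml::write_yaml(plain, path)
  } else stopf("unsupported config format: .%s", ext)
  invisible(path)
}

write_csv_plain <- function(df, path) {
  utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

log_stage <- function(log, stage, ...) {
  entry <- list(stage = stage, params = list(...))
  c(log, list(entry))
}

#' Run an end-to-end analysis pipeline on a simulated scene
#'
#' Ties the stages together for one of five modes, writing a reproducible
#' result bundle to `out_dir`: the resolved configuration, per-segment CSV
#' tables, radial histograms, flow/traction fields and a JSON summary.
#' Everything is deterministic given `config$seed`.
#'
#' Modes: `network` (simulate, render, denoise, extract, link, stats),
#' `flow` (uniform advection, PIV flow, mean rate), `rotation` (rigid
#' rotation, angular velocity), `tfm` (bead pair, PIV displacement,
#' regularized FTTC, per-cell ROI stats), `ablation` (cell-group scene:
#' pre/post bundles for [report_ablation()]).
#'
#' @param config a [run_config()].
#' @param mode one of `"network"`, `"flow"`, `"rotation"`, `"tfm"`,
#'   `"ablation"`.
#' @param out_dir output directory (created if missing).
#' @return invisible list (class `keratrack_bundle`) with the computed
#'   objects and file paths.
#' @export
run_pipeline <- function(config, mode = c("network", "flow", "rotation",
                                          "tfm", "ablation"),
                         out_dir = tempfile("keratrack_")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(out_dir, "resolved_config.json"))
  log <- list()
  psz <- config$pixel_size_um
  geom <- make_micropattern(config$pattern$shape,
                            diameter_um = config$pattern$diameter_um,
                            pixel_size_um = psz,
                            image_shape = config$pattern$image_shape)
  log <- log_stage(log, "micropattern", shape = config$pattern$shape)
  bundle <- list(mode = mode, out_dir = out_dir, config = config)

  analyze_network <- function(scene, tag = "") {
    stk <- render_network_stack(scene)
    den <- denoise_stack(stk, "gaussian", sigma_px = 1)
    ridge <- ridge_enhance(den, config$extraction$scales_px)
    segs <- extract_centerlines(ridge, tau = config$extraction$tau,
                                spacing_px = config$extraction$spacing_px,
                                min_length_px = config$extraction$min_length_px,
                                intensity_stack = den)
    net <- link_nodes(segs, config$linking_epsilon_px, psz)
    stats_df <- segment_stats(segs)
    ori <- segment_orientation_vectors(segs)
    hist <- radial_histogram(ori)
    write_csv_plain(stats_df, file.path(out_dir, paste0("segment_stats", tag, ".csv")))
    write_csv_plain(data.frame(bin_start_deg = hist$bin_start_deg,
                               weight = hist$weight),
                    file.path(out_dir, paste0("radial_histogram", tag, ".csv")))
    seg_rows <- do.call(rbind, lapply(segs, function(s)
      data.frame(segment_id = s$segment_id,
                 vertex_index = seq_len(nrow(s$vertices)),
                 x_um = s$vertices[, 1], y_um = s$vertices[, 2],
                 z_um = s$vertices[, 3])))
    write_csv_plain(seg_rows %||% data.frame(), file.path(out_dir, paste0("segments", tag, ".csv")))
    list(scene = scene, stack = stk, segments = segs, network = net,
         stats = stats_df, histogram = hist)
  }

  if (mode == "network") {
    net_truth <- simulate_filament_network(geom, n_curves = config$n_curves,
                                           seed = config$seed)
    scene <- synthetic_scene(geom, network = net_truth, seed = config$seed,
                             substrate = config$substrate)
    res <- analyze_network(scene)
    summary <- list(mode = mode, n_segments = length(res$segments),
                    n_nodes = nrow(res$network$nodes),
                    mean_length_um = mean(res$stats$length_um),
                    mean_curvature_per_um = mean(res$stats$curvature_per_um, na.rm = TRUE),
                    sum_vector_um = res$histogram$sum_vector, seed = config$seed)
    bundle <- c(bundle, res)
  } else if (mode == "flow") {
    net_truth <- simulate_filament_network(geom, n_curves = config$n_curves,
                                           margin_um = 3, seed = config$seed)
    scene <- synthetic_scene(geom, network = net_truth, seed = config$seed)
    fs <- simulate_flow_series(scene, config$flow$speed_um_min,
                               config$flow$n_frames, config$dt_min,
                               mode = config$flow$mode)
    fields <- lapply(seq_len(config$flow$n_frames - 1), function(t)
      compute_flow_field(fs$stack$voxels[t, , , ], fs$stack$voxels[t + 1, , , ],
                         config$piv$window_px, config$piv$overlap,
                         mask = geom$mask, dt_min = config$dt_min,
                         pixel_size_um = psz))
    rate <- mean_flow_rate(fields, mask = geom$mask, center_px = geom$center_px)
    write_csv_plain(do.call(rbind, lapply(seq_along(fields), function(i) {
      df <- as.data.frame(fields[[i]]); df$frame_pair <- i; df
    })), file.path(out_dir, "flow_field.csv"))
    write_csv_plain(rate$radial_profile, file.path(out_dir, "radial_profile.csv"))
    summary <- list(mode = mode, mean_rate_um_min = rate$mean_rate_um_min,
                    fraction_invalid = rate$fraction_invalid,
                    truth_speed_um_min = config$flow$speed_um_min,
                    seed = config$seed)
    bundle <- c(bundle, list(series = fs, fields = fields, rate = rate))
  } else if (mode == "rotation") {
    net_truth <- simulate_filament_network(geom, n_curves = config$n_curves,
                                           margin_um = 3, seed = config$seed)
    scene <- synthetic_scene(geom, network = net_truth, seed = config$seed)
    fs <- simulate_flow_series(scene, mode = "rotation",
                               omega_deg_per_frame = config$rotation$omega_deg_per_frame,
                               n_frames = config$rotation$n_frames,
                               dt_min = config$rotation$dt_min)
    rot <- rotation_rate(fs, center_px = geom$center_px,
                         dt_min = config$rotation$dt_min,
                         window_px = config$piv$window_px,
                         overlap = config$piv$overlap)
    write_csv_plain(as.data.frame(rot$mean_field),
                    file.path(out_dir, "mean_piv_field.csv"))
    summary <- list(mode = mode, omega_deg_h = rot$omega_deg_h,
                    sign = rot$sign,
                    truth_omega_deg_h = config$rotation$omega_deg_per_frame *
                      60 / config$rotation$dt_min, seed = config$seed)
    bundle <- c(bundle, list(series = fs, rotation = rot))
  } else if (mode == "tfm") {
    scene <- simulate_cell_group(geom, n_cells = config$ablation$n_cells,
                                 seed = config$seed,
                                 substrate = config$substrate)
    ts <- simulate_traction_scene(scene)
    disp <- piv_displacement(ts$reference, ts$stressed,
                             config$piv$window_px, config$piv$overlap)
    tf <- reconstruct_traction(disp, E_pa = config$substrate$E_pa,
                               nu = config$substrate$nu, lambda = config$lambda)
    roi <- lapply(scene$cells$masks, function(m)
      roi_traction_stats(tf, grid_mask_from_image(m, tf)))
    tf_df <- data.frame(x_px = rep(tf$x_px, each = length(tf$y_px)),
                        y_px = rep(tf$y_px, times = length(tf$x_px)),
                        tx_pa = as.vector(tf$tx), ty_pa = as.vector(tf$ty))
    write_csv_plain(tf_df, file.path(out_dir, "traction.csv"))
    write_stack(image_stack(traction_magnitude(tf), psz, channel = "traction_pa"),
                file.path(out_dir, "traction_magnitude.tif"))
    summary <- list(mode = mode,
                    mean_traction_pa = mean(traction_magnitude(tf)),
                    roi_mean_pa = vapply(roi, `[[`, 0, "mean_pa"),
                    lambda = config$lambda, E_pa = config$substrate$E_pa,
                    nu = config$substrate$nu, seed = config$seed)
    bundle <- c(bundle, list(scene = scene, traction_scene = ts,
                             displacement = disp, traction = tf, roi = roi))
  } else if (mode == "ablation") {
    scene <- simulate_cell_group(geom, n_cells = config$ablation$n_cells,
                                 seed = config$seed,
                                 substrate = config$substrate)
    post_scene <- simulate_ablation(scene, config$ablation$cell,
                                    config$ablation$traction_scale)
    run_one <- function(sc, tag) {
      res <- analyze_network(sc, tag)
      ts <- simulate_traction_scene(sc)
      disp <- piv_displacement(ts$reference, ts$stressed,
                               config$piv$window_px, config$piv$overlap)
      tf <- reconstruct_traction(disp, E_pa = config$substrate$E_pa,
                                 nu = config$substrate$nu, lambda = config$lambda)
      roi <- lapply(sc$cells$masks, function(m)
        roi_traction_stats(tf, grid_mask_from_image(m, tf)))
      den <- denoise_stack(res$stack, "gaussian", sigma_px = 1)
      part <- analyze_cells_cropped(den, sc$cells$masks, config)
      c(res, list(traction = tf, roi = roi, partition = part))
    }
    pre <- run_one(scene, "_pre")
    post <- run_one(post_scene, "_post")
    summary <- list(mode = mode,
                    roi_mean_pre_pa = vapply(pre$roi, `[[`, 0, "mean_pa"),
                    roi_mean_post_pa = vapply(post$roi, `[[`, 0, "mean_pa"),
                    traction_scale = config$ablation$traction_scale,
                    ablated_cell = config$ablation$cell, seed = config$seed)
    bundle <- c(bundle, list(pre = pre, post = post))
  }
  bundle$summary <- summary
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  class(bundle) <- "keratrack_bundle"
  invisible(bundle)
}

## Per-cell extraction on territory-masked crops. Cropping and masking each
## cell's subimage makes the per-cell statistics strictly local: analyses of
## one cell are unaffected by changes elsewhere on the pattern (the per-cell
## analog of analyzing "individual cells and their surroundings" separately).
analyze_cells_cropped <- function(den, masks, config, margin_px = 8L) {
  psz <- den$pixel_size_um
  stats_list <- lapply(masks, function(m) {
    idx <- which(m, arr.ind = TRUE)
    if (!nrow(idx)) return(segment_stats(list()))
    y0 <- max(1L, min(idx[, 1]) - margin_px); y1 <- min(nrow(m), max(idx[, 1]) + margin_px)
    x0 <- max(1L, min(idx[, 2]) - margin_px); x1 <- min(ncol(m), max(idx[, 2]) + margin_px)
    dil <- !erode_mask(!m, 2)
    sub <- den
    crop <- den$voxels[, y0:y1, x0:x1, drop = FALSE]
    mc <- dil[y0:y1, x0:x1]
    for (z in seq_len(dim(crop)[1])) crop[z, , ] <- crop[z, , ] * mc
    sub$voxels <- crop
    ridge <- ridge_enhance(sub, config$extraction$scales_px)
    segs <- extract_centerlines(ridge, tau = config$extraction$tau,
                                spacing_px = config$extraction$spacing_px,
                                min_length_px = config$extraction$min_length_px,
                                intensity_stack = sub)
    segs <- lapply(segs, function(s) {
      s$vertices[, 1] <- s$vertices[, 1] + (x0 - 1) * psz
      s$vertices[, 2] <- s$vertices[, 2] + (y0 - 1) * psz
      s
    })
    keep <- vapply(segs, function(s) {
      xp <- round(s$vertices[, 1] / psz) + 1L
      yp <- round(s$vertices[, 2] / psz) + 1L
      ok <- xp >= 1 & xp <= ncol(m) & yp >= 1 & yp <= nrow(m)
      if (!any(ok)) return(0)
      mean(m[cbind(yp[ok], xp[ok])])
    }, 0)
    segment_stats(segs[keep > 0.5])
  })
  list(stats = stats_list)
}

## Downsample an image-resolution logical mask onto a traction/PIV grid.
grid_mask_from_image <- function(mask, tf) {
  xs <- pmin(pmax(round(tf$x_px), 0), ncol(mask) - 1) + 1
  ys <- pmin(pmax(round(tf$y_px), 0), nrow(mask) - 1) + 1
  outer(seq_along(ys), seq_along(xs), function(i, j) mask[cbind(ys[i], xs[j])])
}

#' Compare a pre/post photoablation bundle pair
#'
#' Pairs the per-cell segment statistics (length and curvature distributions
#' with Mann-Whitney p-values), the orientation sum vectors, and the ROI
#' traction means of two `ablation`-mode bundles (or two bundles from
#' [run_pipeline()] with identical geometry).
#'
#' @param pre_bundle,post_bundle results of an `ablation` run
#'   ([run_pipeline()]) or its `pre`/`post` components.
#' @return list of class `ablation_report`: `traction` (per-cell data
#'   frame with pre/post means and relative reduction), `segments` (per-cell
#'   length/curvature comparisons), `sum_vectors`.
#' @export
report_ablation <- function(pre_bundle, post_bundle) {
  pre <- if (!is.null(pre_bundle$pre)) pre_bundle$pre else pre_bundle
  post <- if (!is.null(pre_bundle$post) && missing(post_bundle)) pre_bundle$post else post_bundle
  if (length(pre$roi) != length(post$roi)) stopf("mismatched cell counts")
  n_cells <- length(pre$roi)
  traction <- data.frame(
    cell = seq_len(n_cells),
    pre_mean_pa = vapply(pre$roi, `[[`, 0, "mean_pa"),
    post_mean_pa = vapply(post$roi, `[[`, 0, "mean_pa"))
  traction$reduction <- 1 - traction$post_mean_pa / traction$pre_mean_pa
  seg_cmp <- lapply(seq_len(n_cells), function(i) {
    a <- pre$partition$stats[[i]]; b <- post$partition$stats[[i]]
    if (!nrow(a) || !nrow(b))
      return(list(cell = i, n_pre = nrow(a), n_post = nrow(b),
                  p_length = NA_real_, p_curvature = NA_real_))
    list(cell = i, n_pre = nrow(a), n_post = nrow(b),
         p_length = compare_groups(a$length_um, b$length_um)$p_value,
         p_curvature = compare_groups(
           a$curvature_per_um[is.finite(a$curvature_per_um)],
           b$curvature_per_um[is.finite(b$curvature_per_um)])$p_value,
         mean_length_pre = mean(a$length_um), mean_length_post = mean(b$length_um),
         mean_curv_pre = mean(a$curvature_per_um, na.rm = TRUE),
         mean_curv_post = mean(b$curvature_per_um, na.rm = TRUE))
  })
  sum_vectors <- list(pre = pre$histogram$sum_vector,
                      post = post$histogram$sum_vector)
  structure(list(traction = traction, segments = seg_cmp,
                 sum_vectors = sum_vectors),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("<ablation_report>\n")
  cat(sprintf("  mean ROI traction reduction: %.1f%%\n",
              100 * mean(x$traction$reduction)))
  print(x$traction, row.names = FALSE)
  invisible(x)
}
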