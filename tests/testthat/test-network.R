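test_that("segment length is the endpoint chord distance", {
  s <- filament_segment(1, rbind(c(0, 0, 0), c(1, 1, 0), c(3, 4, 0)))
  expect_identical(segment_length(s), 5)
  expect_identical(segment_length(filament_segment(2, rbind(c(0, 0, 0), c(0, 0, 2)))), 2)
  ## random polylines: equals the closed-form endpoint distance, and the
  ## chord never exceeds the arc length (equality iff collinear)
  set.seed(21)
  for (i in 1:20) {
    s <- random_segment(i, n = 10)
    V <- s$vertices
    expect_equal(segment_length(s), sqrt(sum((V[10, ] - V[1, ])^2)))
    expect_lte(segment_length(s), segment_arclength(s) + 1e-12)
  }
  col <- filament_segment(99, cbind(seq(0, 5, by = 0.5), seq(0, 10, by = 1), 0))
  expect_lt(abs(segment_length(col) - segment_arclength(col)), 1e-9)
  expect_error(filament_segment(1, rbind(c(0, 0, 0))), "2 vertices")
})

test_that("curvature matches circle and helix closed forms and flags short chains", {
  th <- seq(0, 2 * pi, length.out = 3000)
  circ <- cbind(10 * cos(th), 10 * sin(th), 0)
  expect_lt(abs(segment_curvature(circ, resample_ds_um = 0.5) - 0.1) / 0.1, 0.02)
  ## collinear
  line <- cbind(seq(0, 10, by = 0.3), 2 * seq(0, 10, by = 0.3), 0)
  expect_lt(segment_curvature(line, 0.5), 1e-6)
  ## helix a=3, c=4: kappa = a/(a^2+c^2) = 0.12
  t <- seq(0, 4 * pi, length.out = 2000)
  helix <- cbind(3 * cos(t), 3 * sin(t), 4 * t)
  expect_lt(abs(segment_curvature(helix, 0.25) - 0.12) / 0.12, 0.02)
  ## too-short chain is flagged, not silently wrong
  short <- segment_curvature(rbind(c(0, 0, 0), c(0.1, 0, 0)), 0.25)
  expect_true(is.nan(short))
  expect_match(attr(short, "reason"), "sample|support")
})

test_that("curvature error at least halves as the resampling step halves", {
  th <- seq(0, 2 * pi, length.out = 3000)
  circ <- cbind(10 * cos(th), 10 * sin(th), 0)
  errs <- vapply(c(0.5, 0.25, 0.125),
                 function(ds) abs(segment_curvature(circ, ds) - 0.1), 0)
  expect_lte(errs[2], errs[1] / 2)
  expect_lte(errs[3], errs[2] / 2)
  ## with a fixed physical smoothing sigma the error still decreases
  errs_f <- vapply(c(0.5, 0.25, 0.125),
                   function(ds) abs(segment_curvature(circ, ds, 0.5) - 0.1), 0)
  expect_true(all(diff(errs_f) <= 1e-9))
})

test_that("node linking equals brute-force single linkage on random instances", {
  ## constructed pairs
  s1 <- filament_segment(1, rbind(c(0, 0, 0), c(5, 0, 0)))
  s2 <- filament_segment(2, rbind(c(6, 0, 0), c(10, 0, 0)))
  net <- link_nodes(list(s1, s2), epsilon_px = 2, pixel_size_um = 1)
  expect_identical(nrow(net$nodes), 1L)
  expect_identical(net$nodes$degree, 2L)
  far <- link_nodes(list(s1, filament_segment(2, rbind(c(8, 0, 0), c(10, 0, 0)))),
                    epsilon_px = 2, pixel_size_um = 1)
  expect_identical(nrow(far$nodes), 0L)
  ## randomized property: identical partition to the O(n^2) oracle,
  ## deterministic under input reordering
  set.seed(31)
  for (rep in 1:30) {
    segs <- lapply(1:sample(3:10, 1), random_segment)
    eps <- stats::runif(1, 0.5, 4)
    net <- link_nodes(segs, eps, 1)
    expect_identical(network_node_strings(net, segs),
                     brute_force_nodes(segs, eps))
    perm <- sample(length(segs))
    net_p <- link_nodes(segs[perm], eps, 1)
    expect_identical(network_node_strings(net_p, segs),
                     network_node_strings(net, segs))
  }
})

test_that("orientation vectors are endpoint chords with an axial option", {
  s <- filament_segment(1, rbind(c(0, 0, 0), c(1, 0, 0)))
  ori <- segment_orientation_vectors(list(s))
  expect_equal(c(ori$vx_um, ori$vy_um, ori$angle_deg), c(1, 0, 0))
  ## axial apolarity: chords at 10 and 190 degrees coincide
  a <- filament_segment(1, rbind(c(0, 0, 0), c(cos(10 * pi / 180), sin(10 * pi / 180), 0)))
  b <- filament_segment(2, rbind(c(0, 0, 0), -c(cos(10 * pi / 180), sin(10 * pi / 180), 0)))
  ax <- segment_orientation_vectors(list(a, b), polarity = "axial")
  expect_equal(ax$angle_deg[1], ax$angle_deg[2], tolerance = 1e-9)
  ## random set equals endpoint subtraction
  set.seed(5)
  segs <- lapply(1:10, random_segment)
  ori <- segment_orientation_vectors(segs)
  for (i in 1:10) {
    V <- segs[[i]]$vertices
    expect_equal(c(ori$vx_um[i], ori$vy_um[i]), unname(V[nrow(V), 1:2] - V[1, 1:2]))
  }
})

test_that("radial histograms are magnitude weighted with an exact sum vector", {
  ## 4-fold symmetry cancels
  v4 <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  h4 <- radial_histogram(v4)
  expect_equal(h4$sum_vector, c(0, 0))
  expect_equal(sum(h4$weight), 4)
  ## parallel vectors add up
  ang <- 30 * pi / 180
  vp <- matrix(rep(c(cos(ang), sin(ang)), each = 10), ncol = 2)
  hp <- radial_histogram(vp)
  expect_equal(hp$sum_magnitude, 10)
  expect_equal(hp$sum_angle_deg, 30)
  ## linearity + permutation invariance on random sets
  set.seed(8)
  V <- matrix(stats::rnorm(40), ncol = 2)
  hv <- radial_histogram(V)
  expect_equal(hv$sum_vector, colSums(V))
  expect_equal(radial_histogram(V[sample(20), ])$sum_vector, hv$sum_vector)
  expect_equal(radial_histogram(2 * V)$sum_vector, 2 * hv$sum_vector)
  ## empty input
  h0 <- radial_histogram(matrix(numeric(0), 0, 2))
  expect_equal(h0$sum_vector, c(0, 0))
  expect_true(all(h0$weight == 0))
  expect_error(radial_histogram(V, n_bins = 3), "n_bins")
})

test_that("per-cell partition assigns by vertex majority and rejects overlap", {
  m1 <- matrix(FALSE, 40, 40); m1[, 1:20] <- TRUE
  m2 <- matrix(FALSE, 40, 40); m2[, 21:40] <- TRUE
  left <- filament_segment(1, cbind(c(2, 8), c(5, 5), 0))
  right <- filament_segment(2, cbind(c(25, 30), c(5, 5), 0))
  ## straddler: 3 of 5 vertices on the left
  strad <- filament_segment(3, cbind(c(16, 17, 18, 21, 22), rep(10, 5), 0))
  out <- filament_segment(4, cbind(c(60, 70), c(5, 5), 0))
  part <- per_cell_partition(list(left, right, strad, out), list(m1, m2),
                             pixel_size_um = 1)
  expect_identical(vapply(part$per_cell[[1]], `[[`, 0L, "segment_id"), c(1L, 3L))
  expect_identical(vapply(part$per_cell[[2]], `[[`, 0L, "segment_id"), 2L)
  expect_identical(vapply(part$unassigned, `[[`, 0L, "segment_id"), 4L)
  expect_identical(nrow(part$stats[[2]]), 1L)
  m_bad <- m1; m_bad[, 15:25] <- TRUE
  expect_error(per_cell_partition(list(left), list(m_bad, m2), 1), "overlap")
})

test_that("Mann-Whitney comparison gives exact small-sample p-values and symmetry", {
  cg <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_identical(unname(cg$U), 0)
  expect_equal(cg$p_value, 0.1)     # exhaustive: 2/choose(6,3) * 2... = 0.1
  expect_gte(compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4))$p_value, 0.99)
  ## U flips to n1*n2 - U when groups swap
  set.seed(2)
  a <- stats::rnorm(6); b <- stats::rnorm(7) + 1
  expect_equal(compare_groups(b, a)$U, 42 - compare_groups(a, b)$U)
  expect_error(compare_groups(numeric(0), 1), "nonempty")
})
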