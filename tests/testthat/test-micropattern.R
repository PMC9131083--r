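test_that("disc mask area matches the analytic disc", {
  mp <- make_micropattern("disc", 47, 0.23, c(256, 256))
  expected <- pi * (47 / 2)^2 / 0.23^2
  expect_lt(abs(sum(mp$mask) - expected) / expected, 0.01)
  ## centroid at the requested center within half a pixel
  idx <- which(mp$mask, arr.ind = TRUE)
  expect_lt(abs(mean(idx[, 2] - 1) - mp$center_px[1]), 0.5)
  expect_lt(abs(mean(idx[, 1] - 1) - mp$center_px[2]), 0.5)
})

test_that("stripe mask is a band of exactly round(width/pixel_size) rows", {
  st <- make_micropattern("stripe", pixel_size_um = 0.5,
                          image_shape = c(128, 128), stripe_width_um = 20)
  rows <- which(rowSums(st$mask) > 0)
  expect_identical(length(rows), as.integer(round(20 / 0.5)))
  expect_identical(rows, min(rows):max(rows))           # contiguous band
  expect_true(all(st$mask[rows, ]))                     # full width
})

test_that("D shape is a half disc cut by a chord through the center", {
  d <- make_micropattern("D", 30, 0.25, c(160, 160))
  disc <- make_micropattern("disc", 30, 0.25, c(160, 160))
  X <- matrix(rep(0:(160 - 1), each = 160), 160, 160)
  expect_identical(d$mask, disc$mask & (X >= d$center_px[1]))
  expect_lt(abs(sum(d$mask) / sum(disc$mask) - 0.5), 0.02)
})

test_that("patterns larger than the frame are rejected", {
  expect_error(make_micropattern("disc", 47, 0.23, c(128, 128)), "does not fit")
  expect_error(make_micropattern("stripe", pixel_size_um = 0.1,
                                 image_shape = c(64, 64),
                                 stripe_width_um = 20), "does not fit")
  expect_error(make_micropattern("disc", -5, 0.23, c(128, 128)), "positive")
})

test_that("mask erosion shrinks masks and respects the frame border", {
  mp <- make_micropattern("disc", 20, 0.25, c(128, 128))
  er <- keratrack:::erode_mask(mp$mask, 4)
  expect_true(all(mp$mask[er]))
  expect_lt(sum(er), sum(mp$mask))
  ## eroded disc radius shrinks by about the erosion radius
  idx <- which(er, arr.ind = TRUE)
  r_max <- max(sqrt((idx[, 2] - 1 - mp$center_px[1])^2 +
                      (idx[, 1] - 1 - mp$center_px[2])^2))
  expect_lt(r_max, 20 / 2 / 0.25 - 4 + 1.5)
})
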