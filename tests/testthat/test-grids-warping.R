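test_that("trilinear sampling is exact on the lattice and on trilinear functions", {
  set.seed(1)
  v <- as_volume(array(runif(5^3, 0, 255), c(5, 5, 5)))
  lattice <- as.matrix(expand.grid(0:4, 0:4, 0:4))
  expect_equal(trilinear_sample(v, lattice), as.numeric(unclass(v)),
               tolerance = 1e-12)

  # midpoint of two adjacent voxels
  v2 <- as_volume(array(0, c(2, 2, 2)) + 0)
  v2[2, 1, 1] <- 10
  expect_equal(trilinear_sample(as_volume(unclass(v2)), rbind(c(0.5, 0, 0))), 5)

  # trilinear interpolation reproduces f(x,y,z) = 1 + 2x + 3y - z exactly
  lv <- linear_volume(c(6, 6, 6), a = 1, b = 2, c = 3, d0 = -1)
  pts <- matrix(runif(300, 0.2, 4.8), ncol = 3)
  expected <- 1 + 2 * pts[, 1] + 3 * pts[, 2] - pts[, 3]
  expect_equal(trilinear_sample(lv, pts), expected, tolerance = 1e-5)

  expect_error(trilinear_sample(lv, rbind(c(NA, 1, 1))),
               class = "progreg_invalid_input")
})

test_that("warp_image handles identity, integer translation, and linear images exactly", {
  set.seed(2)
  m <- as_volume(array(runif(8^3), c(8, 8, 8)))
  expect_equal(unclass(warp_image(m, zero_flow(c(8, 8, 8)))), unclass(m),
               tolerance = 1e-14, ignore_attr = TRUE)

  shifted <- warp_image(m, constant_flow(c(8, 8, 8), c(1, 0, 0)))
  expect_equal(unclass(shifted)[1:7, , ], unclass(m)[2:8, , ],
               tolerance = 1e-14, ignore_attr = TRUE)
  # clamp-to-edge at the top boundary
  expect_equal(unclass(shifted)[8, , ], unclass(m)[8, , ],
               tolerance = 1e-14, ignore_attr = TRUE)

  # exactness on a linear ramp image under a smooth flow
  ramp <- ramp_volume(c(8, 8, 8))
  u <- smooth_test_flow(c(8, 8, 8), amplitude = 2, seed = 3)
  warped <- warp_image(ramp, u)
  co <- expand.grid(d = 0:7, h = 0:7, w = 0:7)
  expected <- pmin(pmax(co$d + as.numeric(unclass(u)[1, , , ]), 0), 7)
  expect_equal(as.numeric(unclass(warped)), expected, tolerance = 1e-5)

  expect_error(warp_image(m, zero_flow(c(8, 8, 4))),
               class = "progreg_invalid_input")
})

test_that("warp_image tracks interpolation depth and the warp counter", {
  m <- as_volume(array(runif(4^3), c(4, 4, 4)))
  u <- zero_flow(c(4, 4, 4))
  reset_warp_count()
  expect_identical(interp_depth(m), 0L)
  w1 <- warp_image(m, u)
  w2 <- warp_image(w1, u)
  expect_identical(interp_depth(w1), 1L)
  expect_identical(interp_depth(w2), 2L)
  expect_identical(warp_count(), 2L)
})

test_that("warp_labels uses nearest-neighbour lookup with floor(x + 0.5) ties", {
  set.seed(3)
  lab <- as_label_map(array(sample(0:3, 6^3, replace = TRUE), c(6, 6, 6)))
  expect_identical(unclass(warp_labels(lab, zero_flow(c(6, 6, 6)))), unclass(lab))

  shifted <- warp_labels(lab, constant_flow(c(6, 6, 6), c(1, 0, 0)))
  expect_identical(unclass(shifted)[1:5, , ], unclass(lab)[2:6, , ])

  # brute-force oracle including the exact-0.5 tie (rounds up)
  u <- array(0, c(3, 6, 6, 6))
  u[1, , , ] <- 0.5
  u[2, , , ] <- -0.49
  warped <- warp_labels(lab, as_flow(u))
  oracle <- array(0L, c(6, 6, 6))
  for (d in 1:6) for (h in 1:6) for (w in 1:6) {
    id <- min(max(floor((d - 1) + 0.5 + 0.5), 0), 5) + 1
    ih <- min(max(floor((h - 1) - 0.49 + 0.5), 0), 5) + 1
    oracle[d, h, w] <- unclass(lab)[id, ih, w]
  }
  expect_identical(unclass(warped), oracle)

  # no label appears that was absent from the input
  uu <- smooth_test_flow(c(6, 6, 6), amplitude = 3, seed = 9)
  expect_true(all(label_ids(warp_labels(lab, uu)) %in% label_ids(lab)))
})

test_that("downsampling is 2x2x2 average pooling", {
  const <- as_volume(array(4.25, c(8, 8, 8)))
  down <- downsample_volume(const)
  expect_equal(dim(down), c(4L, 4L, 4L))
  expect_true(all(abs(unclass(down) - 4.25) < 1e-14))

  # the full working resolution halves to 96 x 80 x 96
  big <- as_volume(array(0, c(192L, 160L, 192L)))
  expect_equal(dim(downsample_volume(big)), c(96L, 80L, 96L))

  # block means of a linear ramp along axis 0
  ramp <- ramp_volume(c(8, 8, 8))
  pooled <- downsample_volume(ramp)
  expect_equal(unclass(pooled)[, 1, 1], c(0.5, 2.5, 4.5, 6.5), tolerance = 1e-12)

  expect_error(downsample_volume(as_volume(array(0, c(6, 7, 6)))),
               class = "progreg_invalid_input")
})

test_that("flow upsampling doubles the grid and the displacements", {
  expect_equal(unclass(upsample_flow(zero_flow(c(8, 8, 8)))),
               unclass(zero_flow(c(16, 16, 16))), ignore_attr = TRUE)

  cf <- constant_flow(c(8, 8, 8), c(1.5, 0, -2))
  up <- upsample_flow(cf)
  expect_equal(dim(up), c(3L, 16L, 16L, 16L))
  expect_true(max(abs(unclass(up)[1, , , ] - 3)) < 1e-12)
  expect_true(max(abs(unclass(up)[2, , , ])) < 1e-12)
  expect_true(max(abs(unclass(up)[3, , , ] + 4)) < 1e-12)

  # linear low-scale field: closed form on interior fine voxels
  s <- 0.1
  lin <- array(0, c(3, 8, 8, 8))
  lin[1, , , ] <- array(rep(s * (0:7), 64), c(8, 8, 8))
  upl <- upsample_flow(as_flow(lin))
  fine <- 1:14  # fine voxels whose coarse coordinate is not clamped
  expected <- 2 * s * ((fine + 0.5) / 2 - 0.5)
  expect_equal(unclass(upl)[1, fine + 1, 4, 4], expected, tolerance = 1e-5)
})

test_that("label maps of downsampled grids subsample block origins", {
  lab <- as_label_map(array(rep(c(1L, 2L), each = 4), c(8, 8, 8)))
  down <- downsample_labels(lab)
  expect_equal(dim(down), c(4L, 4L, 4L))
  expect_identical(unclass(down)[, 1, 1], c(1L, 1L, 2L, 2L))
})

test_that("type constructors validate their invariants", {
  expect_error(as_volume(array(0, c(4, 4))), class = "progreg_invalid_input")
  expect_error(as_volume(array(c(NA, rep(0, 26)), c(3, 3, 3))),
               class = "progreg_invalid_input")
  expect_error(as_flow(array(0, c(2, 4, 4, 4))), class = "progreg_invalid_input")
  expect_error(as_label_map(array(-1L, c(3, 3, 3))),
               class = "progreg_invalid_input")
  expect_identical(label_ids(as_label_map(array(c(0L, 2L, 5L), c(3, 1, 1)))),
                   c(2L, 5L))
})
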