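cube_mask_labels <- function(shape, from, to, label = 1L) {
  x <- array(0L, shape)
  x[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- label
  as_label_map(x)
}

test_that("dice counts overlap as 2|A∩B| / (|A| + |B|)", {
  a <- cube_mask_labels(c(6, 6, 6), c(1, 1, 1), c(2, 2, 2))
  expect_equal(dice(a, a, 1), 1)

  b <- cube_mask_labels(c(6, 6, 6), c(4, 4, 4), c(5, 5, 5))
  expect_equal(dice(a, b, 1), 0)

  # two 2x2x2 cubes sharing a 1x2x2 slab: 2*4 / (8 + 8) = 0.5
  c1 <- cube_mask_labels(c(6, 6, 6), c(1, 1, 1), c(2, 2, 2))
  c2 <- cube_mask_labels(c(6, 6, 6), c(2, 1, 1), c(3, 2, 2))
  expect_equal(dice(c1, c2, 1), 0.5)
  expect_equal(dice(c2, c1, 1), 0.5)  # symmetry

  # label absent from both maps scores 1 by convention
  expect_equal(dice(a, a, 9), 1)
  expect_error(dice(a, cube_mask_labels(c(4, 4, 4), c(1, 1, 1), c(2, 2, 2)), 1),
               class = "progreg_invalid_input")
})

test_that("dice_report aggregates per-label scores with an unweighted mean", {
  single <- cube_mask_labels(c(6, 6, 6), c(1, 1, 1), c(3, 3, 3))
  rep1 <- dice_report(single, single)
  expect_identical(rep1$n_labels, 1L)
  expect_equal(rep1$mean, 1)

  # label 1 perfect, label 2 disjoint -> mean 0.5
  a <- array(0L, c(8, 8, 8)); b <- array(0L, c(8, 8, 8))
  a[1:2, 1:2, 1:2] <- 1L; b[1:2, 1:2, 1:2] <- 1L
  a[5:6, 5:6, 5:6] <- 2L; b[7:8, 7:8, 7:8] <- 2L
  rep2 <- dice_report(as_label_map(a), as_label_map(b))
  expect_equal(unname(rep2$per_label), c(1, 0))
  expect_equal(rep2$mean, 0.5)

  # random 3-label fixture against a per-voxel counting oracle
  set.seed(31)
  la <- as_label_map(array(sample(0:3, 10^3, replace = TRUE), c(10, 10, 10)))
  lb <- as_label_map(array(sample(0:3, 10^3, replace = TRUE), c(10, 10, 10)))
  rep3 <- dice_report(la, lb)
  for (l in 1:3) {
    na <- 0; nb <- 0; ni <- 0
    for (i in 1:1000) {
      va <- unclass(la)[[i]]; vb <- unclass(lb)[[i]]
      na <- na + (va == l); nb <- nb + (vb == l); ni <- ni + (va == l && vb == l)
    }
    expect_equal(unname(rep3$per_label[as.character(l)]), 2 * ni / (na + nb))
  }

  expect_error(dice_report(as_label_map(array(0L, c(4, 4, 4))),
                           as_label_map(array(0L, c(4, 4, 4)))),
               class = "progreg_invalid_input")
})

test_that("edge sharpness measures the boundary gradient and drops under blurring", {
  # binary step of height 5 along axis 0
  step <- array(0, c(10, 10, 10))
  step[6:10, , ] <- 5
  v <- as_volume(step)
  band <- array(FALSE, c(10, 10, 10))
  band[5, , ] <- TRUE  # voxels whose forward difference crosses the step
  expect_equal(edge_sharpness(v, band), 5)

  # constant volume has zero sharpness everywhere
  flat <- as_volume(array(3, c(10, 10, 10)))
  expect_equal(edge_sharpness(flat, band), 0)

  blurred <- as_volume(progreg:::gauss_blur3(step, 1))
  wide <- array(FALSE, c(10, 10, 10)); wide[4:7, , ] <- TRUE
  expect_lt(edge_sharpness(blurred, wide), edge_sharpness(v, wide))

  expect_error(edge_sharpness(v, array(FALSE, c(10, 10, 10))),
               class = "progreg_invalid_input")
})

test_that("boundary_band marks voxels adjacent to label boundaries", {
  lab <- cube_mask_labels(c(12, 12, 12), c(3, 3, 3), c(8, 8, 8))
  band <- boundary_band(lab, halo = 1)
  expect_true(band[3, 5, 5])    # just inside the face
  expect_true(band[2, 5, 5])    # one-voxel halo outside
  expect_false(band[12, 12, 12])  # far background
  expect_false(band[6, 5, 5])   # deep interior beyond the halo
})
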