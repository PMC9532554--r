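test_that("lncc scores self-similarity and positive affine maps as 1", {
  set.seed(8)
  a <- as_volume(array(runif(8^3, 0, 255), c(8, 8, 8)))
  expect_equal(lncc(a, a, 5), 1, tolerance = 1e-4)
  expect_equal(lncc(a, as_volume(3 * unclass(a) + 7), 5), 1, tolerance = 1e-4)
  # symmetry and bounds
  b <- as_volume(array(runif(8^3, 0, 255), c(8, 8, 8)))
  expect_equal(lncc(a, b, 5), lncc(b, a, 5), tolerance = 1e-12)
  expect_true(abs(lncc(a, b, 5)) <= 1 + 1e-12)
  neg <- as_volume(255 - unclass(a))
  expect_equal(lncc(a, neg, 5), -1, tolerance = 1e-4)

  expect_error(lncc(a, b, 4), class = "progreg_invalid_input")
  expect_error(lncc(a, b, 9), class = "progreg_invalid_input")
})

test_that("lncc matches a brute-force per-window oracle", {
  vals <- 0:124
  set.seed(9)
  a <- array(as.numeric(vals), c(5, 5, 5))
  b <- array(as.numeric(sample(vals)), c(5, 5, 5))
  window <- 3L
  r <- 1L
  eps <- 1e-5
  total <- 0
  for (d in 1:5) for (h in 1:5) for (w in 1:5) {
    ds <- max(1, d - r):min(5, d + r)
    hs <- max(1, h - r):min(5, h + r)
    ws <- max(1, w - r):min(5, w + r)
    pa <- as.numeric(a[ds, hs, ws])
    pb <- as.numeric(b[ds, hs, ws])
    n <- length(pa)
    cov <- mean(pa * pb) - mean(pa) * mean(pb)
    va <- mean(pa^2) - mean(pa)^2
    vb <- mean(pb^2) - mean(pb)^2
    total <- total + cov / sqrt((va + eps) * (vb + eps))
  }
  oracle <- total / 125
  expect_equal(lncc(as_volume(a), as_volume(b), window), oracle, tolerance = 1e-10)
})

test_that("smooth_energy is zero for constants, quadratic, and matches a ramp oracle", {
  expect_identical(smooth_energy(constant_flow(c(6, 6, 6), c(4, -2, 9))), 0)

  u <- smooth_test_flow(c(8, 8, 8), seed = 13)
  expect_equal(smooth_energy(as_flow(2.5 * unclass(u))), 2.5^2 * smooth_energy(u),
               tolerance = 1e-10)

  # ramp s*x along axis 0 in component 1 on an 8^3 grid
  s <- 0.7
  ur <- array(0, c(3, 8, 8, 8))
  ur[1, , , ] <- array(rep(s * (0:7), 64), c(8, 8, 8))
  # oracle: explicit forward-difference loop
  total <- 0; count <- 0
  for (comp in 1:3) for (ax in 1:3) {
    n <- 8
    for (d in 1:8) for (h in 1:8) for (w in 1:8) {
      idx <- c(d, h, w)
      if (idx[ax] < n) {
        nxt <- idx; nxt[ax] <- nxt[ax] + 1
        diffv <- ur[comp, nxt[1], nxt[2], nxt[3]] - ur[comp, d, h, w]
        total <- total + diffv^2
        count <- count + 1
      }
    }
  }
  expect_equal(smooth_energy(as_flow(ur)), total / count, tolerance = 1e-12)
  # closed form for this ramp: s^2 at (D-1)*H*W sites over the full normalizer
  expect_equal(smooth_energy(as_flow(ur)), s^2 * (7 * 64) / (3 * 3 * 7 * 64),
               tolerance = 1e-12)
})

test_that("the objective is -LNCC + lambda * smoothness, on the newest flow only", {
  set.seed(10)
  f <- as_volume(array(runif(8^3, 0, 255), c(8, 8, 8)))
  u <- smooth_test_flow(c(8, 8, 8), seed = 14)
  w <- loss_weights(0.7, 5)

  # perfect alignment with a constant (zero-penalty) flow scores -1
  expect_equal(registration_objective(f, f, constant_flow(c(8, 8, 8), c(1, 2, 3)), w),
               -1, tolerance = 1e-4)

  # lambda = 0 reduces to -lncc exactly
  m <- as_volume(array(runif(8^3, 0, 255), c(8, 8, 8)))
  expect_identical(registration_objective(m, f, u, loss_weights(0, 5)),
                   -lncc(m, f, 5))

  # additivity against independent component calls
  expect_equal(registration_objective(m, f, u, w),
               -lncc(m, f, 5) + 0.7 * smooth_energy(u), tolerance = 1e-6)

  # the penalty sees only the newest flow: any other aggregate history with
  # the same warped output leaves the objective unchanged
  o1 <- registration_objective(m, f, u, w)
  o2 <- registration_objective(m, f, u, w)
  expect_identical(o1, o2)

  expect_error(registration_objective(m, as_volume(array(1, c(4, 4, 4))), u, w),
               class = "progreg_invalid_input")
})

test_that("loss weights validate their domain", {
  expect_error(loss_weights(-1, 5), class = "progreg_invalid_input")
  expect_error(loss_weights(1, 4), class = "progreg_invalid_input")
  expect_error(loss_weights(1, 1), class = "progreg_invalid_input")
})
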