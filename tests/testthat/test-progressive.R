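make_test_pair16 <- function(seed = 1, amplitude = 3) {
  pspec <- phantom_spec(shape = c(16, 16, 16), n_structures = 2, seed = seed)
  make_pair(pspec, deformation_spec(amplitude, 3, seed = seed + 10))
}

test_that("a single pass reduces to one-shot registration", {
  p <- make_test_pair16()
  net <- jittered_backbone()
  res <- progressive_infer(p$moving, p$fixed, net, n_test = 1,
                           weights = loss_weights(1, 5))
  expect_identical(unclass(res$total_flow),
                   unclass(predict_flow(p$moving, p$fixed, net)))
  ref <- warp_image(p$moving, res$total_flow)
  expect_lt(max(abs(unclass(res$warped) - unclass(ref))), 1e-6)
  expect_identical(res$interp_count, 1L)
})

test_that("a zero-weight backbone leaves the moving image untouched for any pass count", {
  p <- make_test_pair16()
  net <- zeroed_backbone()
  for (k in c(1L, 3L)) {
    res <- progressive_infer(p$moving, p$fixed, net, n_test = k,
                             weights = loss_weights(1, 5))
    expect_true(all(unclass(res$total_flow) == 0))
    expect_lt(max(abs(unclass(res$warped) - unclass(p$moving))), 1e-9)
  }
  hres <- hierarchical_infer(p$moving, p$fixed, zeroed_backbone(), net,
                             iteration_schedule(1, 2), iteration_schedule(1, 2),
                             loss_weights(1, 5))
  expect_true(all(unclass(hres$total_flow) == 0))
  expect_lt(max(abs(unclass(hres$warped) - unclass(p$moving))), 1e-9)
})

test_that("the final output is always one interpolation of the primary moving image", {
  p <- make_test_pair16()
  net <- jittered_backbone()
  w <- loss_weights(1, 5)
  for (k in 1:5) {
    reset_warp_count()
    res <- progressive_infer(p$moving, p$fixed, net, n_test = k, weights = w)
    expect_identical(res$interp_count, 1L)
    expect_identical(warp_count(), k)  # one warp of the primary per pass
  }
  # the sequential cascade compounds interpolations instead
  for (k in c(2L, 4L)) {
    cas <- cascade_infer(p$moving, p$fixed, net, n_test = k, weights = w)
    expect_identical(cas$interp_count, k)
  }
})

test_that("the aggregate equals the fold of the per-pass flows, and the warp is recomputable", {
  p <- make_test_pair16(seed = 3)
  net <- jittered_backbone(seed = 9)
  w <- loss_weights(1, 5)
  res <- progressive_infer(p$moving, p$fixed, net, n_test = 3, weights = w)
  refold <- compose_chain(res$flows)
  expect_lt(max(abs(unclass(refold) - unclass(res$total_flow))), 1e-10)
  expect_lt(max(abs(unclass(warp_image(p$moving, res$total_flow)) -
                    unclass(res$warped))), 1e-6)

  hres <- hierarchical_infer(p$moving, p$fixed, jittered_backbone(seed = 4), net,
                             iteration_schedule(1, 2), iteration_schedule(1, 2), w)
  expect_identical(hres$interp_count, 1L)
  expect_lt(max(abs(unclass(compose_chain(hres$flows)) - unclass(hres$total_flow))),
            1e-10)
  expect_lt(max(abs(unclass(warp_image(p$moving, hres$total_flow)) -
                    unclass(hres$warped))), 1e-6)
})

test_that("update granularity: per-pass updates apply one Adam step per pass", {
  p <- make_test_pair16()
  w <- loss_weights(1, 5)
  cfg_pp <- train_config(steps = 1, lr = 1e-3, seed = 0, weights = w,
                         schedule = iteration_schedule(3, 1))
  st <- train_state(cfg_pp, tiny_backbone_config())
  out <- train_step(p$moving, p$fixed, st, cfg_pp)
  expect_identical(out$state$opt$t, 3L)
  expect_identical(nrow(out$diagnostics), 3L)

  cfg_sw <- train_config(steps = 1, lr = 1e-3, seed = 0, weights = w,
                         schedule = iteration_schedule(3, 1), update = "sweep")
  st2 <- train_state(cfg_sw, tiny_backbone_config())
  out2 <- train_step(p$moving, p$fixed, st2, cfg_sw)
  expect_identical(out2$state$opt$t, 1L)

  # one shared parameter set: every pass updates the same named tensors
  expect_identical(names(out$state$net$params), names(st$net$params))
})

test_that("n_train = 1 training is a standard one-shot registration step", {
  p <- make_test_pair16()
  cfg <- train_config(steps = 1, lr = 1e-3, seed = 0,
                      weights = loss_weights(1, 5),
                      schedule = iteration_schedule(1, 1))
  st <- train_state(cfg, tiny_backbone_config())
  out <- train_step(p$moving, p$fixed, st, cfg)
  expect_identical(nrow(out$diagnostics), 1L)
  expect_identical(out$state$opt$t, 1L)
})

test_that("training reduces the objective on a small fixture", {
  p <- make_test_pair16(seed = 2, amplitude = 4)
  cfg <- train_config(steps = 40, lr = 1e-3, seed = 0,
                      weights = loss_weights(1, 5),
                      schedule = iteration_schedule(3, 3))
  fit <- train_progressive(list(p), cfg, backbone_config())
  h <- fit$history
  first <- mean(h$objective[h$step <= 10])
  last <- mean(h$objective[h$step > 30])
  expect_lt(last, first)
})

test_that("hierarchical phase 2 with zero steps returns the untrained initialization", {
  pairs <- list(make_test_pair16(seed = 5))
  w <- loss_weights(1, 5)
  cfg_low <- train_config(steps = 2, lr = 1e-3, seed = 0, weights = w,
                          schedule = iteration_schedule(1, 1))
  cfg_orig <- train_config(steps = 1, lr = 1e-3, seed = 3, weights = w,
                           schedule = iteration_schedule(1, 1))
  cfg_orig$steps <- 0L  # phase isolation
  fit <- train_hierarchical(pairs, cfg_low, cfg_orig, tiny_backbone_config())
  expect_identical(fit$net_orig$params,
                   init_backbone(tiny_backbone_config(), seed = 3)$params)
})

test_that("phase 2 never mutates the frozen low-scale weights", {
  pairs <- list(make_test_pair16(seed = 6))
  w <- loss_weights(1, 5)
  cfg_low <- train_config(steps = 2, lr = 1e-3, seed = 0, weights = w,
                          schedule = iteration_schedule(2, 1))
  cfg_orig <- train_config(steps = 2, lr = 1e-3, seed = 1, weights = w,
                           schedule = iteration_schedule(2, 1))
  low_only <- train_progressive(
    lapply(pairs, function(p) list(moving = downsample_volume(p$moving),
                                   fixed = downsample_volume(p$fixed))),
    cfg_low, tiny_backbone_config())
  fit <- train_hierarchical(pairs, cfg_low, cfg_orig, tiny_backbone_config())
  checksum <- function(net) sum(vapply(net$params, function(p) sum(abs(p$w)) + sum(abs(p$b)), 0))
  expect_equal(checksum(fit$net_low), checksum(low_only$net), tolerance = 1e-12)
})

test_that("schedules and configs validate their domain", {
  expect_error(iteration_schedule(0, 1), class = "progreg_invalid_input")
  expect_error(train_config(lr = 0), class = "progreg_invalid_input")
  expect_error(train_config(steps = 0), class = "progreg_invalid_input")
  p <- make_test_pair16()
  expect_error(progressive_infer(p$moving, p$fixed, jittered_backbone(), n_test = 0),
               class = "progreg_invalid_input")
})
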