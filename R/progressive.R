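#' Iteration schedule of the progressive chain
#'
#' Numbers of shared-weight network passes used during training and at
#' inference. The two counts are independent hyperparameters: a model trained
#' with `n_train` passes may be evaluated at any `n_test`. A count of 1 is
#' the one-shot (non-progressive) baseline.
#'
#' @param n_train passes per training step (>= 1).
#' @param n_test passes at inference (>= 1).
#' @return an `iteration_schedule` list.
#' @export
iteration_schedule <- function(n_train = 1L, n_test = 1L) {
  n_train <- as.integer(n_train)
  n_test <- as.integer(n_test)
  if (n_train < 1L || n_test < 1L)
    stop_invalid("iteration counts must be >= 1")
  structure(list(n_train = n_train, n_test = n_test), class = "iteration_schedule")
}

#' Training configuration
#'
#' @param steps total optimization steps (>= 1); 30000 at full working
#'   resolution, 150-300 for desk-scale fixtures.
#' @param lr Adam learning rate (default 1e-4, the full-scale setting; desk
#'   fixtures use 1e-3 to converge within a few hundred steps).
#' @param batch registration pairs consumed per step.
#' @param seed RNG seed controlling weight initialization.
#' @param weights a [loss_weights()] object.
#' @param schedule an [iteration_schedule()].
#' @param update `"per_pass"` applies one Adam update after every progressive
#'   pass (the per-iteration objective is backpropagated as soon as the pass
#'   completes); `"sweep"` accumulates gradients over all passes of a step and
#'   applies a single update.
#' @return a `train_config` list.
#' @export
train_config <- function(steps = 300L, lr = 1e-4, batch = 1L, seed = 0L,
                         weights = loss_weights(), schedule = iteration_schedule(),
                         update = c("per_pass", "sweep")) {
  update <- match.arg(update)
  if (lr <= 0) stop_invalid("learning rate must be > 0")
  if (steps < 1L) stop_invalid("steps must be >= 1")
  if (batch < 1L) stop_invalid("batch must be >= 1")
  structure(list(steps = as.integer(steps), lr = lr, batch = as.integer(batch),
                 seed = as.integer(seed), weights = weights, schedule = schedule,
                 update = update),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) list(w = array(0, dim(p$w)), b = numeric(length(p$b)))),
       v = lapply(params, function(p) list(w = array(0, dim(p$w)), b = numeric(length(p$b)))),
       t = 0L)
}

adam_update <- function(net, grads, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    for (part in c("w", "b")) {
      g <- grads[[nm]][[part]]
      opt$m[[nm]][[part]] <- beta1 * opt$m[[nm]][[part]] + (1 - beta1) * g
      opt$v[[nm]][[part]] <- beta2 * opt$v[[nm]][[part]] + (1 - beta2) * g * g
      step <- lr * (opt$m[[nm]][[part]] / c1) /
        (sqrt(opt$v[[nm]][[part]] / c2) + eps)
      net$params[[nm]][[part]] <- net$params[[nm]][[part]] - step
    }
  }
  list(net = net, opt = opt)
}

# One internal warp of the primary (normalized) moving image; bumps the
# process-wide warp counter like warp_image does.
warp_primary <- function(m4, agg) {
  .progreg$warp_count <- .progreg$warp_count + 1L
  .cpp_warp_trilinear(m4, agg)
}

# Forward + loss (+ optional gradient) of one progressive pass operating on
# raw normalized arrays. `agg` is the detached running aggregate or NULL.
pass_eval <- function(net, m4, cur, f, agg, w, grad = TRUE) {
  fwd <- net_forward(net, cur, f, tape = grad)
  flow_n <- fwd$flow
  if (is.null(agg)) {
    agg_new <- flow_n
    prev_ch <- NULL
  } else {
    prev_ch <- aperm(agg, c(2L, 3L, 4L, 1L))
    agg_new <- flow_n + aperm(.cpp_warp_trilinear(prev_ch, flow_n), c(4L, 1L, 2L, 3L))
  }
  warped4 <- warp_primary(m4, agg_new)
  warped <- array(warped4, dim(f))
  sim <- mean(lncc_parts(warped, f, w$lncc_window)$cc)
  sm <- smooth_energy(flow_n)
  obj <- -sim + w$lambda_smooth * sm
  out <- list(flow_n = flow_n, agg = agg_new, warped = warped,
              similarity = sim, smoothness = sm, objective = obj)
  if (grad) {
    gw <- -lncc_grad_b(f, warped, w$lncc_window)
    gw4 <- array(gw, c(dim(f), 1L))
    g_agg <- .cpp_warp_trilinear_bwd_flow(m4, agg_new, gw4)
    g_flow <- if (is.null(prev_ch)) g_agg else {
      gch <- aperm(g_agg, c(2L, 3L, 4L, 1L))
      g_agg + .cpp_warp_trilinear_bwd_flow(prev_ch, flow_n, gch)
    }
    if (w$lambda_smooth > 0)
      g_flow <- g_flow + w$lambda_smooth * smooth_energy_grad(flow_n)
    out$grads <- net_backward(net, fwd$tape, g_flow)
  }
  out
}

#' One self-calibrating training step
#'
#' Runs `n_train` progressive passes on a single registration pair. At pass
#' `n`, the network sees the (gradient-detached) result of pass `n - 1` and
#' the fixed image, predicts the newest field, aggregates it with the
#' detached running total, warps the primary moving image once, and evaluates
#' the per-pass objective with the smoothness penalty on the newest field
#' only. Under the default `"per_pass"` update mode, one Adam step is applied
#' after every pass; gradients never flow through earlier passes.
#'
#' @param moving,fixed `volume`s of one training pair.
#' @param state list with elements `net` (a `backbone`) and `opt` (Adam
#'   state); create with [train_state()].
#' @param cfg a [train_config()].
#' @param init_flow optional `flow` used as the initial aggregate (the
#'   upsampled coarse-scale output during hierarchical training); the chain
#'   then starts from the correspondingly pre-warped moving image.
#' @return list with the updated `state` and a `diagnostics` data frame of
#'   per-pass similarity, smoothness, and objective.
#' @export
train_step <- function(moving, fixed, state, cfg, init_flow = NULL) {
  nf <- normalize_pair(moving, fixed)
  w <- cfg$weights
  n_train <- cfg$schedule$n_train
  m4 <- array(nf$m, c(dim(nf$m), 1L))
  agg <- NULL
  cur <- nf$m
  if (!is.null(init_flow)) {
    agg <- unclass(as_flow(init_flow))
    cur <- array(warp_primary(m4, agg), dim(nf$m))
  }
  acc <- NULL
  diags <- vector("list", n_train)
  for (pass in seq_len(n_train)) {
    ev <- pass_eval(state$net, m4, cur, nf$f, agg, w, grad = TRUE)
    if (!is.finite(ev$objective))
      stop(errorCondition(
        sprintf("non-finite objective at pass %d", pass),
        class = c("progreg_training_error", "error")))
    if (cfg$update == "per_pass") {
      upd <- adam_update(state$net, ev$grads, state$opt, cfg$lr)
      state$net <- upd$net
      state$opt <- upd$opt
    } else {
      acc <- if (is.null(acc)) ev$grads else
        mapply(function(a, g) list(w = a$w + g$w, b = a$b + g$b),
               acc, ev$grads, SIMPLIFY = FALSE)
    }
    diags[[pass]] <- data.frame(pass = pass, similarity = ev$similarity,
                                smoothness = ev$smoothness, objective = ev$objective)
    agg <- ev$agg
    cur <- ev$warped
  }
  if (cfg$update == "sweep") {
    acc <- lapply(acc, function(a) list(w = a$w / n_train, b = a$b / n_train))
    upd <- adam_update(state$net, acc, state$opt, cfg$lr)
    state$net <- upd$net
    state$opt <- upd$opt
  }
  list(state = state, diagnostics = do.call(rbind, diags))
}

#' Create a fresh training state
#'
#' @param cfg a [train_config()]; its seed controls weight initialization.
#' @param backbone_cfg a [backbone_config()].
#' @return list with a `net` and Adam optimizer state `opt`.
#' @export
train_state <- function(cfg, backbone_cfg = backbone_config()) {
  net <- init_backbone(backbone_cfg, seed = cfg$seed)
  list(net = net, opt = adam_init(net$params))
}

#' Train a progressive registration model on a set of pairs
#'
#' Cycles deterministically through the training pairs, applying
#' [train_step()] at each optimization step.
#'
#' @param pairs list of pairs, each a list with `moving` and `fixed` volumes
#'   (as produced by [make_pair()]).
#' @param cfg a [train_config()].
#' @param backbone_cfg a [backbone_config()] for the fresh model.
#' @param init_flows optional list parallel to `pairs` of initial aggregate
#'   flows (hierarchical phase-2 training).
#' @return list with the trained `net` and a `history` data frame.
#' @export
train_progressive <- function(pairs, cfg, backbone_cfg = backbone_config(),
                              init_flows = NULL) {
  state <- train_state(cfg, backbone_cfg)
  history <- vector("list", cfg$steps)
  n <- length(pairs)
  idx <- 0L
  for (step in seq_len(cfg$steps)) {
    hrows <- vector("list", cfg$batch)
    for (bi in seq_len(cfg$batch)) {
      idx <- (idx %% n) + 1L
      res <- train_step(pairs[[idx]]$moving, pairs[[idx]]$fixed, state, cfg,
                        init_flow = if (is.null(init_flows)) NULL else init_flows[[idx]])
      state <- res$state
      d <- res$diagnostics
      d$step <- step
      d$pair <- idx
      hrows[[bi]] <- d
    }
    history[[step]] <- do.call(rbind, hrows)
  }
  list(net = state$net, history = do.call(rbind, history))
}

new_registration_result <- function(total_flow, warped, per_pass, flows = NULL) {
  structure(list(total_flow = as_flow(total_flow), warped = warped,
                 per_pass = per_pass, flows = flows,
                 interp_count = interp_depth(warped)),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result: %d passes, final similarity %.4f, interpolations of the moving image: %d>\n",
              nrow(x$per_pass), x$per_pass$similarity[nrow(x$per_pass)], x$interp_count))
  invisible(x)
}

# Rebuild a volume from a normalized warped array, undoing the joint [0,1]
# map; the result is exactly one interpolation of the primary moving image.
denorm_volume <- function(warped_norm, lo, hi, template) {
  v <- if (hi > lo) warped_norm * (hi - lo) + lo else warped_norm + lo
  structure(array(v, dim(warped_norm)),
            spacing = attr(template, "spacing"),
            interp_depth = 1L,
            class = c("volume", "array"))
}

#' Progressive inference with aggregate-flow composition
#'
#' Applies the shared-weight network `n_test` times. At pass `k` the network
#' registers the previous pass's output to the fixed image; the new field is
#' composed onto the running aggregate, and the primary moving image is
#' warped once by the aggregate. The final output is therefore produced by a
#' single interpolation of the primary moving image regardless of `n_test`.
#'
#' @param moving,fixed `volume`s of identical shape.
#' @param net a trained `backbone`.
#' @param n_test number of passes (>= 1).
#' @param weights [loss_weights()] used for the per-pass diagnostics.
#' @param init_flow optional initial aggregate `flow` (hierarchical cascade).
#' @return a `registration_result` with the total flow, the once-warped
#'   moving image, per-pass diagnostics, and the interpolation count.
#' @export
progressive_infer <- function(moving, fixed, net, n_test = 1L,
                              weights = loss_weights(), init_flow = NULL) {
  n_test <- as.integer(n_test)
  if (n_test < 1L) stop_invalid("n_test must be >= 1")
  moving <- as_volume(moving)
  fixed <- as_volume(fixed)
  check_same_shape(dim(moving), dim(fixed), "progressive_infer")
  nf <- normalize_pair(moving, fixed)
  lo <- min(unclass(moving), unclass(fixed))
  hi <- max(unclass(moving), unclass(fixed))
  m4 <- array(nf$m, c(dim(nf$m), 1L))
  agg <- NULL
  cur <- nf$m
  if (!is.null(init_flow)) {
    agg <- unclass(as_flow(init_flow))
    cur <- array(warp_primary(m4, agg), dim(nf$m))
  }
  diags <- vector("list", n_test)
  flows <- if (is.null(init_flow)) list() else list(as_flow(init_flow))
  for (k in seq_len(n_test)) {
    ev <- pass_eval(net, m4, cur, nf$f, agg, weights, grad = FALSE)
    diags[[k]] <- data.frame(pass = k, similarity = ev$similarity,
                             smoothness = ev$smoothness, objective = ev$objective)
    flows[[length(flows) + 1L]] <- as_flow(ev$flow_n)
    agg <- ev$agg
    cur <- ev$warped
  }
  warped <- denorm_volume(cur, lo, hi, moving)
  new_registration_result(agg, warped, do.call(rbind, diags), flows = flows)
}

#' Conventional sequential-cascade inference (information-lossy baseline)
#'
#' The recursive-cascade alternative to [progressive_infer()]: every pass
#' warps the already-warped image again, so the output accumulates one
#' interpolation per pass and progressively blurs sharp boundaries. Provided
#' for quantifying the information-loss effect; not the recommended
#' inference path.
#'
#' @inheritParams progressive_infer
#' @return a `registration_result` whose `interp_count` equals `n_test`.
#' @export
cascade_infer <- function(moving, fixed, net, n_test = 1L,
                          weights = loss_weights()) {
  n_test <- as.integer(n_test)
  if (n_test < 1L) stop_invalid("n_test must be >= 1")
  moving <- as_volume(moving)
  fixed <- as_volume(fixed)
  check_same_shape(dim(moving), dim(fixed), "cascade_infer")
  nf <- normalize_pair(moving, fixed)
  lo <- min(unclass(moving), unclass(fixed))
  hi <- max(unclass(moving), unclass(fixed))
  cur <- moving
  cur_norm <- nf$m
  flows <- vector("list", n_test)
  diags <- vector("list", n_test)
  for (k in seq_len(n_test)) {
    flow_k <- as_flow(net_forward(net, cur_norm, nf$f)$flow)
    cur <- warp_image(cur, flow_k)  # warp of a warp: interpolation compounds
    cur_norm <- if (hi > lo) (unclass(cur) - lo) / (hi - lo) else unclass(cur)
    flows[[k]] <- flow_k
    diags[[k]] <- data.frame(pass = k,
                             similarity = mean(lncc_parts(cur_norm, nf$f, weights$lncc_window)$cc),
                             smoothness = smooth_energy(flow_k),
                             objective = NA_real_)
  }
  new_registration_result(compose_chain(flows), cur, do.call(rbind, diags),
                          flows = flows)
}

#' Two-scale coarse-to-fine inference
#'
#' Downsamples the pair by 2, runs the low-scale progressive chain, upsamples
#' its aggregate (doubling both grid and displacements) as the initial value
#' of the original-scale chain, then runs the original-scale passes. The
#' low-scale aggregate is part of the total field, so the final output is
#' still produced by one interpolation of the primary moving image.
#'
#' @param moving,fixed `volume`s; extents divisible by `2^(levels + 1)`.
#' @param net_low,net_orig trained `backbone`s for the two scales.
#' @param sched_low,sched_orig [iteration_schedule()]s; the defaults (5/3 and
#'   9/2) are the grid-search optima at full working resolution.
#' @param weights [loss_weights()] for diagnostics.
#' @return a `registration_result` at the original scale.
#' @export
hierarchical_infer <- function(moving, fixed, net_low, net_orig,
                               sched_low = iteration_schedule(5L, 3L),
                               sched_orig = iteration_schedule(9L, 2L),
                               weights = loss_weights()) {
  moving <- as_volume(moving)
  fixed <- as_volume(fixed)
  check_same_shape(dim(moving), dim(fixed), "hierarchical_infer")
  m_low <- downsample_volume(moving)
  f_low <- downsample_volume(fixed)
  low_window <- min(weights$lncc_window, odd_cap(min(dim(m_low))))
  res_low <- progressive_infer(m_low, f_low, net_low, n_test = sched_low$n_test,
                               weights = loss_weights(weights$lambda_smooth, low_window))
  flow_up <- upsample_flow(res_low$total_flow)
  res <- progressive_infer(moving, fixed, net_orig, n_test = sched_orig$n_test,
                           weights = weights, init_flow = flow_up)
  low_d <- res_low$per_pass
  low_d$scale <- "low"
  orig_d <- res$per_pass
  orig_d$scale <- "original"
  res$per_pass <- rbind(low_d, orig_d)
  res
}

odd_cap <- function(n) if (n %% 2L == 0L) n - 1L else n

#' Two-phase hierarchical training
#'
#' Phase 1 trains the low-scale backbone on 2x-downsampled pairs. Phase 2
#' freezes it, computes for every pair the upsampled low-scale aggregate
#' (inference with `cfg_low$schedule$n_test` passes), and trains the
#' original-scale backbone with each step initialized by that frozen flow.
#'
#' @param pairs list of training pairs (`moving`, `fixed` volumes).
#' @param cfg_low,cfg_orig [train_config()]s for the two phases.
#' @param backbone_cfg shared [backbone_config()] of both scales.
#' @return list with `net_low`, `net_orig`, the two configs, and training
#'   histories.
#' @export
train_hierarchical <- function(pairs, cfg_low, cfg_orig,
                               backbone_cfg = backbone_config()) {
  low_pairs <- lapply(pairs, function(p)
    list(moving = downsample_volume(p$moving), fixed = downsample_volume(p$fixed)))
  phase1 <- train_progressive(low_pairs, cfg_low, backbone_cfg)
  init_flows <- lapply(low_pairs, function(p) {
    low_window <- min(cfg_low$weights$lncc_window, odd_cap(min(dim(p$moving))))
    res <- progressive_infer(p$moving, p$fixed, phase1$net,
                             n_test = cfg_low$schedule$n_test,
                             weights = loss_weights(cfg_low$weights$lambda_smooth, low_window))
    upsample_flow(res$total_flow)
  })
  phase2 <- if (cfg_orig$steps > 0L)
    train_progressive(pairs, cfg_orig, backbone_cfg, init_flows = init_flows)
  else
    list(net = init_backbone(backbone_cfg, seed = cfg_orig$seed), history = NULL)
  list(net_low = phase1$net, net_orig = phase2$net,
       cfg_low = cfg_low, cfg_orig = cfg_orig,
       history_low = phase1$history, history_orig = phase2$history)
}

#' Grid search over training and inference pass counts
#'
#' Trains one progressive model per `n_train` value and evaluates each at
#' every `n_test` value by mean Dice over the evaluation pairs, mirroring the
#' protocol used to select the pass counts at full scale (and, since each
#' added training pass presents the network with a freshly generated warped
#' input, it is also the dynamic-augmentation study: the training set is
#' implicitly doubled per added pass).
#'
#' @param pairs training pairs with `moving`/`fixed` volumes.
#' @param base_cfg a [train_config()]; its schedule is overridden per cell.
#' @param n_train_range,n_test_range integer vectors of pass counts.
#' @param eval_pairs pairs with `moving`, `fixed`, `moving_labels`,
#'   `fixed_labels` used for Dice scoring (defaults to `pairs`).
#' @param backbone_cfg [backbone_config()] of each trained model.
#' @return list with the `|n_train| x |n_test|` mean-Dice `matrix` and the
#'   argmax cell (`best`).
#' @export
grid_search <- function(pairs, base_cfg, n_train_range, n_test_range,
                        eval_pairs = pairs, backbone_cfg = backbone_config()) {
  if (length(n_train_range) == 0L || length(n_test_range) == 0L)
    stop_invalid("grid ranges must be non-empty")
  dice_mat <- matrix(NA_real_, length(n_train_range), length(n_test_range),
                     dimnames = list(paste0("n_train=", n_train_range),
                                     paste0("n_test=", n_test_range)))
  for (i in seq_along(n_train_range)) {
    cfg_i <- base_cfg
    cfg_i$schedule <- iteration_schedule(n_train_range[i], 1L)
    model <- train_progressive(pairs, cfg_i, backbone_cfg)$net
    for (j in seq_along(n_test_range)) {
      scores <- vapply(eval_pairs, function(p) {
        res <- progressive_infer(p$moving, p$fixed, model,
                                 n_test = n_test_range[j], weights = base_cfg$weights)
        dice_report(warp_labels(p$moving_labels, res$total_flow), p$fixed_labels)$mean
      }, 0)
      dice_mat[i, j] <- mean(scores)
    }
  }
  best <- which(dice_mat == max(dice_mat), arr.ind = TRUE)[1, ]
  list(dice = dice_mat,
       n_train_range = n_train_range, n_test_range = n_test_range,
       best = list(n_train = n_train_range[best[1]], n_test = n_test_range[best[2]],
                   dice = max(dice_mat)))
}
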