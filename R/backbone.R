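#' Configuration of the shared-weight flow-prediction network
#'
#' The backbone is a UNet: the encoder applies one stride-2 4x4x4 convolution
#' per resolution stage, and the decoder applies nearest-neighbour x2
#' upsampling followed by stride-1 3x3x3 convolutions, with a second 3x3x3
#' convolution in each of the final two stages for finer detail. Every
#' convolution is followed by a LeakyReLU except the final 3-channel flow
#' head. The same parameter set is reused across all progressive passes.
#'
#' @param levels number of encoder downsamplings (input extents must be
#'   divisible by `2^levels`).
#' @param enc_channels feature widths of the `levels` encoder stages.
#' @param dec_channels `levels + 1` widths: one per decoder stage, plus the
#'   width of the second convolution used in each of the final two stages.
#' @param leaky_slope negative slope of the LeakyReLU activations.
#' @return a `backbone_config` list.
#' @export
backbone_config <- function(levels = 4L,
                            enc_channels = c(16L, 32L, 32L, 32L),
                            dec_channels = c(32L, 32L, 32L, 16L, 16L),
                            leaky_slope = 0.2) {
  levels <- as.integer(levels)
  if (levels < 1L) stop_invalid("levels must be >= 1")
  if (length(enc_channels) != levels)
    stop_invalid("enc_channels must have one width per level")
  if (length(dec_channels) != levels + 1L)
    stop_invalid("dec_channels must have levels + 1 widths")
  structure(list(levels = levels,
                 enc_channels = as.integer(enc_channels),
                 dec_channels = as.integer(dec_channels),
                 leaky_slope = leaky_slope),
            class = "backbone_config")
}

# Layer table implied by a config: name, kernel, stride, pad, cin, cout, act.
backbone_layers <- function(cfg) {
  L <- cfg$levels
  layers <- list()
  cin <- 2L
  for (i in seq_len(L)) {
    layers[[paste0("enc", i)]] <- list(k = 4L, stride = 2L, pad = 1L,
                                       cin = cin, cout = cfg$enc_channels[i], act = TRUE)
    cin <- cfg$enc_channels[i]
  }
  width <- cfg$enc_channels[L]
  extra <- cfg$dec_channels[L + 1L]
  for (i in seq_len(L)) {
    skip <- if (i < L) cfg$enc_channels[L - i] else 2L
    layers[[paste0("dec", i, "a")]] <- list(k = 3L, stride = 1L, pad = 1L,
                                            cin = width + skip,
                                            cout = cfg$dec_channels[i], act = TRUE)
    width <- cfg$dec_channels[i]
    if (i >= L - 1L) {
      layers[[paste0("dec", i, "b")]] <- list(k = 3L, stride = 1L, pad = 1L,
                                              cin = width, cout = extra, act = TRUE)
      width <- extra
    }
  }
  layers[["head"]] <- list(k = 3L, stride = 1L, pad = 1L,
                           cin = width, cout = 3L, act = FALSE)
  layers
}

#' Initialize backbone weights
#'
#' He-style normal initialization scaled by fan-in for all convolutions; the
#' flow head is initialized near zero (sd 1e-5) so an untrained network
#' predicts approximately the identity transform, which stabilizes the first
#' progressive passes.
#'
#' @param cfg a [backbone_config()].
#' @param seed integer RNG seed for reproducible weights.
#' @return a `backbone` object (config plus named parameter list).
#' @export
init_backbone <- function(cfg = backbone_config(), seed = 0L) {
  specs <- backbone_layers(cfg)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  params <- lapply(names(specs), function(nm) {
    s <- specs[[nm]]
    fan_in <- s$k^3 * s$cin
    sd <- if (nm == "head") 1e-5 else sqrt(2 / fan_in)
    list(w = array(stats::rnorm(s$k^3 * s$cin * s$cout, sd = sd),
                   c(s$k, s$k, s$k, s$cin, s$cout)),
         b = numeric(s$cout))
  })
  names(params) <- names(specs)
  structure(list(config = cfg, params = params), class = "backbone")
}

#' Number of trainable parameters of a backbone
#' @param net a `backbone`.
#' @return integer count of weights plus biases.
#' @export
count_parameters <- function(net) {
  sum(vapply(net$params, function(p) length(p$w) + length(p$b), 0))
}

#' @export
print.backbone <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<backbone: %d levels, enc (%s), dec (%s), %d parameters>\n",
              cfg$levels, paste(cfg$enc_channels, collapse = ","),
              paste(cfg$dec_channels, collapse = ","), count_parameters(x)))
  invisible(x)
}

check_divisible <- function(shape, levels) {
  fac <- 2L^levels
  bad <- which(shape %% fac != 0L)
  if (length(bad))
    stop(errorCondition(
      sprintf("extent %d along axis %d is not divisible by 2^levels = %d",
              shape[bad[1]], bad[1], fac),
      class = c("progreg_config_error", "error")))
}

lrelu <- function(x, slope) x * (slope + (1 - slope) * (x > 0))

up2_nn <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L),
    rep(seq_len(d[3]), each = 2L), , drop = FALSE]
}

up2_nn_bwd <- function(g) {
  d <- dim(g)
  dim(g) <- c(2L, d[1] %/% 2L, 2L, d[2] %/% 2L, 2L, d[3] %/% 2L, d[4])
  g <- aperm(g, c(1L, 3L, 5L, 2L, 4L, 6L, 7L))
  dim(g) <- c(8L, length(g) %/% 8L)
  out <- colSums(g)
  dim(out) <- c(d[1] %/% 2L, d[2] %/% 2L, d[3] %/% 2L, d[4])
  out
}

# Forward pass on raw arrays (D,H,W) already intensity-normalized.
# Returns flow array (3,D,H,W) and, if tape = TRUE, the per-conv inputs and
# pre-activations needed by net_backward.
net_forward <- function(net, moving_arr, fixed_arr, tape = FALSE) {
  cfg <- net$config
  L <- cfg$levels
  dm <- dim(moving_arr)
  check_divisible(dm, L)
  specs <- backbone_layers(cfg)
  p <- net$params
  rec <- if (tape) list() else NULL

  conv <- function(nm, x) {
    s <- specs[[nm]]
    z <- .cpp_conv3d_fwd(x, p[[nm]]$w, p[[nm]]$b, s$stride, s$pad)
    if (tape) rec[[nm]] <<- list(x = x, z = if (s$act) z else NULL)
    if (s$act) lrelu(z, cfg$leaky_slope) else z
  }

  x0 <- array(c(moving_arr, fixed_arr), c(dm, 2L))
  e <- vector("list", L)
  h <- x0
  for (i in seq_len(L)) {
    h <- conv(paste0("enc", i), h)
    e[[i]] <- h
  }
  d <- e[[L]]
  for (i in seq_len(L)) {
    d <- up2_nn(d)
    skip <- if (i < L) e[[L - i]] else x0
    d <- array(c(d, skip), c(dim(d)[1:3], dim(d)[4] + dim(skip)[4]))
    d <- conv(paste0("dec", i, "a"), d)
    if (i >= L - 1L) d <- conv(paste0("dec", i, "b"), d)
  }
  y <- conv("head", d)
  list(flow = aperm(y, c(4L, 1L, 2L, 3L)), tape = rec)
}

# Reverse sweep: gradient of a scalar loss with respect to every conv weight
# and bias, given the gradient with respect to the predicted flow (3,D,H,W).
net_backward <- function(net, tape, g_flow) {
  cfg <- net$config
  L <- cfg$levels
  specs <- backbone_layers(cfg)
  p <- net$params
  slope <- cfg$leaky_slope
  grads <- list()

  conv_bwd <- function(nm, gy) {
    s <- specs[[nm]]
    t <- tape[[nm]]
    if (s$act) gy <- gy * (slope + (1 - slope) * (t$z > 0))
    r <- .cpp_conv3d_bwd(t$x, p[[nm]]$w, gy, s$stride, s$pad)
    grads[[nm]] <<- list(w = r$gw, b = r$gb)
    r$gx
  }

  ge <- vector("list", L)  # accumulated encoder-feature gradients
  gd <- conv_bwd("head", aperm(g_flow, c(2L, 3L, 4L, 1L)))
  for (i in rev(seq_len(L))) {
    if (i >= L - 1L) gd <- conv_bwd(paste0("dec", i, "b"), gd)
    gcat <- conv_bwd(paste0("dec", i, "a"), gd)
    nup <- dim(gcat)[4] - (if (i < L) cfg$enc_channels[L - i] else 2L)
    gup <- gcat[, , , seq_len(nup), drop = FALSE]
    gskip <- gcat[, , , (nup + 1L):dim(gcat)[4], drop = FALSE]
    if (i < L) {
      j <- L - i
      ge[[j]] <- if (is.null(ge[[j]])) gskip else ge[[j]] + gskip
    }
    gprev <- up2_nn_bwd(gup)
    if (i == 1L) {
      ge[[L]] <- if (is.null(ge[[L]])) gprev else ge[[L]] + gprev
    } else {
      gd <- gprev
    }
  }
  for (i in rev(seq_len(L))) {
    gx <- conv_bwd(paste0("enc", i), ge[[i]])
    if (i > 1L) ge[[i - 1L]] <- ge[[i - 1L]] + gx
  }
  grads
}

# Joint [0,1] intensity normalization of a registration pair; both images
# share one affine map so relative contrast is preserved across passes.
normalize_pair <- function(moving, fixed) {
  m <- unclass(as_volume(moving))
  f <- unclass(as_volume(fixed))
  lo <- min(m, f)
  hi <- max(m, f)
  if (hi - lo <= 0) {
    m[] <- 0; f[] <- 0
  } else {
    m <- (m - lo) / (hi - lo)
    f <- (f - lo) / (hi - lo)
  }
  list(m = m, f = f)
}

#' Predict a displacement field for one image pair
#'
#' Runs the shared-weight backbone once on a (moving, fixed) pair. Both
#' intensities are jointly rescaled to `[0, 1]` before entering the network.
#' The prediction is deterministic given fixed weights and inputs.
#'
#' @param moving,fixed `volume`s of identical shape, each extent divisible by
#'   `2^levels` of the backbone.
#' @param net a `backbone` from [init_backbone()] or a loaded checkpoint.
#' @return a `flow` of the same spatial shape.
#' @export
predict_flow <- function(moving, fixed, net) {
  moving <- as_volume(moving)
  fixed <- as_volume(fixed)
  check_same_shape(dim(moving), dim(fixed), "predict_flow")
  nf <- normalize_pair(moving, fixed)
  as_flow(net_forward(net, nf$m, nf$f)$flow)
}

#' Save or load a backbone checkpoint
#'
#' The checkpoint is a single RDS file embedding both the configuration and
#' the parameter arrays.
#'
#' @param net a `backbone`.
#' @param path file path of the checkpoint.
#' @return `load_checkpoint` returns the restored `backbone`.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(config = unclass(net$config), params = net$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(backbone_config, obj$config[c("levels", "enc_channels",
                                               "dec_channels", "leaky_slope")])
  structure(list(config = cfg, params = obj$params), class = "backbone")
}
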