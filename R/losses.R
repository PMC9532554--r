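#' Loss weights for the registration objective
#'
#' @param lambda_smooth nonnegative weight of the smoothness penalty relative
#'   to the similarity term.
#' @param lncc_window odd window edge length (voxels) of the local normalized
#'   cross-correlation; 9 at full working resolution, 5 recommended for small
#'   (<= 32^3) desk fixtures.
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(lambda_smooth = 1, lncc_window = 9L) {
  if (lambda_smooth < 0) stop_invalid("lambda_smooth must be >= 0")
  lncc_window <- as.integer(lncc_window)
  if (lncc_window < 3L || lncc_window %% 2L == 0L)
    stop_invalid("lncc_window must be odd and >= 3")
  structure(list(lambda_smooth = lambda_smooth, lncc_window = lncc_window),
            class = "loss_weights")
}

.lncc_eps <- 1e-5

lncc_parts <- function(a, b, window) {
  r <- (window - 1L) %/% 2L
  ones <- array(1, dim(a))
  n <- .cpp_boxsum(ones, r)
  mu_a <- .cpp_boxsum(a, r) / n
  mu_b <- .cpp_boxsum(b, r) / n
  cov <- .cpp_boxsum(a * b, r) / n - mu_a * mu_b
  var_a <- pmax(.cpp_boxsum(a * a, r) / n - mu_a^2, 0)
  var_b <- pmax(.cpp_boxsum(b * b, r) / n - mu_b^2, 0)
  denom <- sqrt((var_a + .lncc_eps) * (var_b + .lncc_eps))
  list(n = n, mu_a = mu_a, mu_b = mu_b, cov = cov,
       var_a = var_a, var_b = var_b, denom = denom, cc = cov / denom)
}

#' Local normalized cross-correlation
#'
#' Windowed similarity between two volumes: at every voxel a cubic window
#' (truncated at the borders) contributes the signed normalized
#' cross-correlation of the two local patches, and the score is the mean over
#' all voxel-centered windows. A small variance guard (1e-5) in the
#' denominator keeps flat windows finite; away from near-constant patches the
#' score is invariant to positive affine intensity rescaling of either
#' argument and equals 1 for identical non-constant inputs.
#'
#' @param a,b `volume`s of identical shape.
#' @param window odd window edge length, at most the smallest extent.
#' @return scalar in `[-1, 1]`.
#' @export
lncc <- function(a, b, window = 9L) {
  a <- as_volume(a); b <- as_volume(b)
  check_same_shape(dim(a), dim(b), "lncc")
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L)
    stop_invalid("window must be odd and >= 3")
  if (window > min(dim(a)))
    stop_invalid("window (", window, ") exceeds the smallest extent (", min(dim(a)), ")")
  mean(lncc_parts(unclass(a), unclass(b), window)$cc)
}

# Gradient of lncc(a, b) with respect to b.  Windows are symmetric
# (q in W_p <=> p in W_q), so the sum over windows containing a voxel is the
# same truncated box sum used forward.
lncc_grad_b <- function(a, b, window) {
  r <- (window - 1L) %/% 2L
  p <- lncc_parts(a, b, window)
  n_win <- length(a)
  a1 <- 1 / (p$n * p$denom)
  a2 <- p$cc / (p$n * (p$var_b + .lncc_eps))
  g <- a * .cpp_boxsum(a1, r) - .cpp_boxsum(a1 * p$mu_a, r) -
    b * .cpp_boxsum(a2, r) + .cpp_boxsum(a2 * p$mu_b, r)
  g / n_win
}

#' Smoothness energy of a displacement field
#'
#' Mean of squared forward differences of the field over all voxels (last
#' slice along each axis excluded), displacement components, and axes. The
#' mean normalization makes the weight `lambda_smooth` comparable across
#' resolutions; the energy is zero iff the field is constant.
#'
#' @param u a `flow`.
#' @return nonnegative scalar.
#' @export
smooth_energy <- function(u) {
  u <- unclass(as_flow(u))
  dm <- dim(u)
  total <- 0
  count <- 0
  for (ax in 2:4) {
    n <- dm[ax]
    idx_hi <- switch(ax - 1,
      u[, 2:n, , , drop = FALSE],
      u[, , 2:n, , drop = FALSE],
      u[, , , 2:n, drop = FALSE])
    idx_lo <- switch(ax - 1,
      u[, 1:(n - 1), , , drop = FALSE],
      u[, , 1:(n - 1), , drop = FALSE],
      u[, , , 1:(n - 1), drop = FALSE])
    d <- idx_hi - idx_lo
    total <- total + sum(d * d)
    count <- count + length(d)
  }
  total / count
}

# Gradient of smooth_energy with respect to u (adjoint of forward differences).
smooth_energy_grad <- function(u) {
  dm <- dim(u)
  g <- array(0, dm)
  count <- sum(vapply(2:4, function(ax) 3 * prod(dm[2:4][-(ax - 1)]) * (dm[ax] - 1), 0))
  for (ax in 2:4) {
    n <- dm[ax]
    if (ax == 2) {
      d <- u[, 2:n, , , drop = FALSE] - u[, 1:(n - 1), , , drop = FALSE]
      g[, 2:n, , ] <- g[, 2:n, , ] + 2 * d
      g[, 1:(n - 1), , ] <- g[, 1:(n - 1), , ] - 2 * d
    } else if (ax == 3) {
      d <- u[, , 2:n, , drop = FALSE] - u[, , 1:(n - 1), , drop = FALSE]
      g[, , 2:n, ] <- g[, , 2:n, ] + 2 * d
      g[, , 1:(n - 1), ] <- g[, , 1:(n - 1), ] - 2 * d
    } else {
      d <- u[, , , 2:n, drop = FALSE] - u[, , , 1:(n - 1), drop = FALSE]
      g[, , , 2:n] <- g[, , , 2:n] + 2 * d
      g[, , , 1:(n - 1)] <- g[, , , 1:(n - 1)] - 2 * d
    }
  }
  g / count
}

#' Per-pass registration objective
#'
#' The unsupervised training loss of one progressive pass:
#' `-lncc(warped_total, fixed) + lambda_smooth * smooth_energy(latest_flow)`.
#' `warped_total` must be the primary moving image warped once by the
#' aggregated field, while the smoothness penalty applies only to the newest
#' per-pass field, never to the aggregate.
#'
#' @param warped_total `volume`: the once-warped moving image.
#' @param fixed `volume`: the registration target.
#' @param latest_flow `flow`: the newest un-aggregated prediction.
#' @param w a [loss_weights()] object.
#' @return scalar loss (lower is better; -1 is a perfect similarity score).
#' @export
registration_objective <- function(warped_total, fixed, latest_flow, w = loss_weights()) {
  warped_total <- as_volume(warped_total)
  fixed <- as_volume(fixed)
  latest_flow <- as_flow(latest_flow)
  check_same_shape(dim(warped_total), dim(fixed), "registration_objective")
  check_same_shape(dim(warped_total), flow_shape(latest_flow), "registration_objective")
  -lncc(warped_total, fixed, w$lncc_window) +
    w$lambda_smooth * smooth_energy(latest_flow)
}
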