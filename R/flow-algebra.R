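#' Compose two displacement fields into one
#'
#' The aggregate-flow operator: given the running total `u_prev` and a newly
#' predicted field `u_next`, returns the single field
#' `u_total(x) = u_next(x) + u_prev(x + u_next(x))`, so that one warp with
#' `u_total` is equivalent (up to interpolation error) to warping with
#' `u_prev` and then with `u_next`. `u_prev` is resampled trilinearly at the
#' displaced positions with clamp-to-edge boundary handling. Composing
#' per-pass fields this way is what lets the progressive chain interpolate
#' the moving image exactly once.
#'
#' @param u_prev a `flow`, the earlier (already aggregated) field.
#' @param u_next a `flow` on the same grid, the newest prediction.
#' @return the composed `flow`.
#' @export
compose_pair <- function(u_prev, u_next) {
  u_prev <- as_flow(u_prev)
  u_next <- as_flow(u_next)
  check_same_shape(flow_shape(u_prev), flow_shape(u_next), "compose_pair")
  prev_ch <- aperm(unclass(u_prev), c(2, 3, 4, 1))  # (D,H,W,3) channel stack
  resampled <- .cpp_warp_trilinear(prev_ch, unclass(u_next))
  as_flow(unclass(u_next) + aperm(resampled, c(4, 1, 2, 3)))
}

#' Fold an ordered chain of displacement fields into one total field
#'
#' Left fold of [compose_pair()]: the first element is the earliest pass's
#' field, and each subsequent field is composed on top of the running
#' aggregate. A chain of `n` fields uses exactly `n - 1` pairwise
#' compositions.
#'
#' @param flows non-empty list of `flow` objects sharing one grid.
#' @return the aggregated `flow`.
#' @export
compose_chain <- function(flows) {
  if (!is.list(flows) || length(flows) == 0L)
    stop_invalid("compose_chain needs a non-empty list of flows")
  agg <- as_flow(flows[[1]])
  for (f in flows[-1]) agg <- compose_pair(agg, f)
  agg
}
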