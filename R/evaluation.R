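#' Dice overlap of one anatomical label
#'
#' `2 |A ∩ B| / (|A| + |B|)` for the voxel masks of `label` in the two maps:
#' 1 means the corresponding regions overlap completely, 0 means they do not
#' overlap at all. If both masks are empty the score is defined as 1.
#'
#' @param warped_labels,fixed_labels `label_map`s of identical shape.
#' @param label the region label to score.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(warped_labels, fixed_labels, label) {
  a <- as_label_map(warped_labels)
  b <- as_label_map(fixed_labels)
  check_same_shape(dim(a), dim(b), "dice")
  ma <- unclass(a) == label
  mb <- unclass(b) == label
  na <- sum(ma)
  nb <- sum(mb)
  if (na + nb == 0L) return(1)
  2 * sum(ma & mb) / (na + nb)
}

#' Per-label Dice report
#'
#' Dice for every nonzero label present in either map, plus their unweighted
#' mean.
#'
#' @param warped_labels,fixed_labels `label_map`s of identical shape.
#' @return a `dice_report` list with `per_label` (named numeric vector),
#'   `mean`, and `n_labels`.
#' @export
dice_report <- function(warped_labels, fixed_labels) {
  a <- as_label_map(warped_labels)
  b <- as_label_map(fixed_labels)
  check_same_shape(dim(a), dim(b), "dice_report")
  labels <- sort(union(label_ids(a), label_ids(b)))
  if (length(labels) == 0L)
    stop_invalid("no nonzero labels to score")
  per <- vapply(labels, function(l) dice(a, b, l), 0)
  names(per) <- labels
  structure(list(per_label = per, mean = mean(per), n_labels = length(labels)),
            class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("<dice_report: %d labels, mean %.4f>\n", x$n_labels, x$mean))
  print(round(x$per_label, 4))
  invisible(x)
}

gradient_magnitude <- function(v) {
  d <- dim(v)
  g2 <- array(0, d)
  dd <- v[c(2:d[1], d[1]), , ] - v
  dd[d[1], , ] <- 0
  g2 <- g2 + dd^2
  dd <- v[, c(2:d[2], d[2]), ] - v
  dd[, d[2], ] <- 0
  g2 <- g2 + dd^2
  dd <- v[, , c(2:d[3], d[3])] - v
  dd[, , d[3]] <- 0
  g2 <- g2 + dd^2
  sqrt(g2)
}

#' Edge sharpness over a boundary band
#'
#' Mean forward-difference gradient magnitude of a volume restricted to a
#' band of edge-adjacent voxels. Repeated interpolation blurs boundaries, so
#' this statistic quantifies the information loss of sequential cascades
#' relative to single-warp aggregation.
#'
#' @param v a `volume`.
#' @param band logical array of the same shape marking the band.
#' @return nonnegative scalar.
#' @export
edge_sharpness <- function(v, band) {
  v <- as_volume(v)
  band <- as.logical(band)
  if (length(band) != length(v))
    stop_invalid("band shape must match the volume")
  if (!any(band))
    stop_invalid("band is empty")
  g <- gradient_magnitude(unclass(v))
  mean(g[band])
}

#' Band of voxels adjacent to label boundaries
#'
#' Marks voxels whose 6-neighbourhood contains a different label, dilated by
#' `halo` voxels. Convenient as the `band` argument of [edge_sharpness()].
#'
#' @param l a `label_map`.
#' @param halo dilation radius in voxels.
#' @return logical array of the label map's shape.
#' @export
boundary_band <- function(l, halo = 1L) {
  x <- unclass(as_label_map(l))
  d <- dim(x)
  b <- array(FALSE, d)
  b[-d[1], , ] <- b[-d[1], , ] | (x[-d[1], , ] != x[-1, , ])
  b[-1, , ] <- b[-1, , ] | (x[-d[1], , ] != x[-1, , ])
  b[, -d[2], ] <- b[, -d[2], ] | (x[, -d[2], ] != x[, -1, ])
  b[, -1, ] <- b[, -1, ] | (x[, -d[2], ] != x[, -1, ])
  b[, , -d[3]] <- b[, , -d[3]] | (x[, , -d[3]] != x[, , -1])
  b[, , -1] <- b[, , -1] | (x[, , -d[3]] != x[, , -1])
  if (halo > 0L) {
    for (i in seq_len(halo)) {
      bb <- b
      bb[-1, , ] <- bb[-1, , ] | b[-d[1], , ]
      bb[-d[1], , ] <- bb[-d[1], , ] | b[-1, , ]
      bb[, -1, ] <- bb[, -1, ] | b[, -d[2], ]
      bb[, -d[2], ] <- bb[, -d[2], ] | b[, -1, ]
      bb[, , -1] <- bb[, , -1] | b[, , -d[3]]
      bb[, , -d[3]] <- bb[, , -d[3]] | b[, , -1]
      b <- bb
    }
  }
  b
}
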