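#' @useDynLib progreg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.progreg <- new.env(parent = emptyenv())
.progreg$warp_count <- 0L

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("progreg_invalid_input", "error")))
}

#' Construct a 3D intensity volume
#'
#' A volume is a 3D scalar grid holding the moving or fixed image of a
#' registration problem. Registration operates in 0-based voxel coordinates
#' with voxel centers at integers; `spacing` is carried as metadata only.
#'
#' @param data numeric 3D array of shape (D, H, W); all extents must be at
#'   least 2 and all intensities finite.
#' @param spacing physical voxel size along each axis (informational).
#' @return an object of class `volume` (a classed array).
#' @export
as_volume <- function(data, spacing = c(1, 1, 1)) {
  if (inherits(data, "volume")) return(data)
  data <- unclass(data)
  if (length(dim(data)) != 3L)
    stop_invalid("a volume must be a 3-d array, got ", length(dim(data)), " dims")
  if (any(dim(data) < 2L))
    stop_invalid("every volume extent must be >= 2")
  if (!all(is.finite(data)))
    stop_invalid("volume intensities must be finite")
  structure(data * 1.0,
            spacing = as.numeric(spacing),
            interp_depth = 0L,
            class = c("volume", "array"))
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume %dx%dx%d, range [%.4g, %.4g], interp depth %d>\n",
              d[1], d[2], d[3], min(x), max(x), interp_depth(x)))
  invisible(x)
}

#' Construct a displacement vector field
#'
#' A flow stores, for every voxel of a (D, H, W) grid, a 3-component
#' displacement in voxel units (components ordered along the D, H, W axes).
#' The deformation field is never stored separately: it is
#' `phi(x) = x + u(x)`, evaluated on demand.
#'
#' @param data numeric 4D array of shape (3, D, H, W) with finite values.
#' @return an object of class `flow`.
#' @export
as_flow <- function(data) {
  if (inherits(data, "flow")) return(data)
  data <- unclass(data)
  dm <- dim(data)
  if (length(dm) != 4L || dm[1] != 3L)
    stop_invalid("a flow must be a (3, D, H, W) array")
  if (!all(is.finite(data)))
    stop_invalid("flow displacements must be finite")
  structure(data * 1.0, class = c("flow", "array"))
}

#' @export
print.flow <- function(x, ...) {
  d <- dim(x)
  mags <- sqrt(colSums(matrix(unclass(x), nrow = 3)^2))
  cat(sprintf("<flow %dx%dx%d, max |u| = %.4g voxels>\n", d[2], d[3], d[4], max(mags)))
  invisible(x)
}

#' Construct an anatomical label map
#'
#' Integer region labels on the same grid as a companion volume; label 0 is
#' reserved for background. Used only for Dice evaluation, never by the
#' registration objective.
#'
#' @param data integer-valued 3D array of non-negative labels.
#' @return an object of class `label_map`.
#' @export
as_label_map <- function(data) {
  if (inherits(data, "label_map")) return(data)
  data <- unclass(data)
  if (length(dim(data)) != 3L)
    stop_invalid("a label map must be a 3-d array")
  if (!all(is.finite(data)) || any(data < 0) || any(data != round(data)))
    stop_invalid("labels must be non-negative integers")
  storage.mode(data) <- "integer"
  structure(data, class = c("label_map", "array"))
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<label_map %dx%dx%d, labels {%s}>\n", d[1], d[2], d[3],
              paste(label_ids(x), collapse = ",")))
  invisible(x)
}

#' Sorted nonzero labels present in a label map
#' @param l a `label_map`.
#' @return sorted integer vector of nonzero labels.
#' @export
label_ids <- function(l) {
  u <- sort(unique(as.integer(l)))
  u[u != 0L]
}

#' @rdname interp_depth
#' @export
interp_depth <- function(v) {
  d <- attr(v, "interp_depth")
  if (is.null(d)) 0L else d
}

#' Interpolation accounting
#'
#' `interp_depth()` reports how many successive interpolations of the primary
#' source image produced a volume (0 for raw data, 1 for a single warp, and so
#' on); repeated resampling of already-resampled data is the mechanism behind
#' cascade blurring, so this depth is the quantity the single-interpolation
#' guarantee constrains. `warp_count()` and `reset_warp_count()` expose a
#' process-wide counter of warp calls used by instrumentation tests.
#'
#' @param v a `volume`.
#' @return `interp_depth`: integer depth; `warp_count`: integer call count.
#' @name interp_depth
NULL

#' @rdname interp_depth
#' @export
warp_count <- function() .progreg$warp_count

#' @rdname interp_depth
#' @export
reset_warp_count <- function() {
  .progreg$warp_count <- 0L
  invisible(NULL)
}

check_same_shape <- function(a_dim, b_dim, what) {
  if (!identical(as.integer(a_dim), as.integer(b_dim)))
    stop_invalid(what, ": spatial shapes differ (",
                 paste(a_dim, collapse = "x"), " vs ", paste(b_dim, collapse = "x"), ")")
}

flow_shape <- function(u) dim(u)[2:4]

#' Trilinear sampling at continuous coordinates
#'
#' Samples a volume at arbitrary continuous positions in 0-based voxel space.
#' Coordinates outside `[0, extent - 1]` are clamped to the boundary before
#' interpolation (clamp-to-edge), so sampling at every integer lattice point
#' reproduces the stored values exactly.
#'
#' @param v a `volume`.
#' @param points numeric matrix with one row per point and 3 columns
#'   (coordinates along the D, H, W axes).
#' @return numeric vector of interpolated intensities, one per point.
#' @export
trilinear_sample <- function(v, points) {
  v <- as_volume(v)
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop_invalid("points must be an n x 3 matrix")
  if (!all(is.finite(points)))
    stop_invalid("point coordinates must be finite")
  .cpp_sample_points(unclass(v), points)
}

#' Backward warping of an image by a displacement field
#'
#' Applies the spatial-transformer resampling `warped(x) = m(x + u(x))` with
#' trilinear interpolation and clamp-to-edge boundary handling. Each call is
#' exactly one interpolation pass: the result's [interp_depth()] is the
#' input's depth plus one, and a process-wide warp counter is incremented.
#'
#' @param m a `volume`, the moving image.
#' @param u a `flow` on the same grid (displacements in voxel units).
#' @return the warped `volume`, same shape as `m`.
#' @export
warp_image <- function(m, u) {
  m <- as_volume(m)
  u <- as_flow(u)
  check_same_shape(dim(m), flow_shape(u), "warp_image")
  x <- unclass(m)
  dim(x) <- c(dim(m), 1L)
  y <- .cpp_warp_trilinear(x, unclass(u))
  dim(y) <- dim(m)
  .progreg$warp_count <- .progreg$warp_count + 1L
  structure(y,
            spacing = attr(m, "spacing"),
            interp_depth = interp_depth(m) + 1L,
            class = c("volume", "array"))
}

#' Nearest-neighbour warping of a label map
#'
#' Looks up the label at `x + u(x)` with the nearest grid index per axis
#' computed as `floor(coordinate + 0.5)` (ties round up), clamped to the
#' volume bounds. The output label set is always a subset of the input's
#' labels plus background.
#'
#' @param l a `label_map`.
#' @param u a `flow` on the same grid.
#' @return the warped `label_map`.
#' @export
warp_labels <- function(l, u) {
  l <- as_label_map(l)
  u <- as_flow(u)
  check_same_shape(dim(l), flow_shape(u), "warp_labels")
  out <- .cpp_warp_nearest(unclass(l), unclass(u))
  structure(out, class = c("label_map", "array"))
}

#' Downsample a volume by average pooling
#'
#' Halves every spatial extent by 2x2x2 mean pooling; constants are preserved
#' exactly. Used to build the coarse scale of the two-scale cascade.
#'
#' @param v a `volume` whose extents are all divisible by 2.
#' @param factor pooling factor; only 2 is supported.
#' @return the pooled `volume` at half resolution.
#' @export
downsample_volume <- function(v, factor = 2L) {
  v <- as_volume(v)
  if (factor != 2L) stop_invalid("only factor 2 downsampling is supported")
  d <- dim(v)
  if (any(d %% 2L != 0L))
    stop_invalid("every extent must be divisible by 2, got ", paste(d, collapse = "x"))
  x <- unclass(v)
  dim(x) <- c(2L, d[1] %/% 2L, 2L, d[2] %/% 2L, 2L, d[3] %/% 2L)
  x <- aperm(x, c(1L, 3L, 5L, 2L, 4L, 6L))
  dim(x) <- c(8L, length(x) %/% 8L)
  pooled <- colMeans(x)
  dim(pooled) <- d %/% 2L
  as_volume(pooled, spacing = attr(v, "spacing") * 2)
}

#' Upsample a low-scale flow to the next finer scale
#'
#' Trilinearly upsamples the field to doubled extents (cell-centered
#' resampling, clamp-to-edge) and multiplies every displacement component by
#' 2, converting coarse-voxel displacements into fine-voxel units. This is
#' the operator that hands the coarse aggregate to the full-resolution chain.
#'
#' @param u a `flow` at the coarse scale.
#' @param factor upsampling factor; only 2 is supported.
#' @return a `flow` with doubled extents and doubled displacements.
#' @export
upsample_flow <- function(u, factor = 2L) {
  u <- as_flow(u)
  if (factor != 2L) stop_invalid("only factor 2 upsampling is supported")
  dl <- flow_shape(u)
  df <- dl * 2L
  # fine voxel centers map to coarse coordinates (i_f + 0.5) / 2 - 0.5
  grid <- as.matrix(expand.grid(d = (seq_len(df[1]) - 0.5) / 2 - 0.5,
                                h = (seq_len(df[2]) - 0.5) / 2 - 0.5,
                                w = (seq_len(df[3]) - 0.5) / 2 - 0.5))
  out <- array(0, c(3L, df))
  for (comp in 1:3) {
    comp_vol <- array(unclass(u)[comp, , , ], dl)
    out[comp, , , ] <- 2 * .cpp_sample_points(comp_vol, grid)
  }
  as_flow(out)
}

#' Downsample a label map by strided subsampling
#'
#' Keeps every second voxel along each axis (the block's origin corner),
#' halving each extent. Companion of [downsample_volume()] for evaluating
#' overlap at the coarse scale.
#'
#' @param l a `label_map` with even extents.
#' @param factor subsampling factor; only 2 is supported.
#' @return the subsampled `label_map`.
#' @export
downsample_labels <- function(l, factor = 2L) {
  l <- as_label_map(l)
  if (factor != 2L) stop_invalid("only factor 2 downsampling is supported")
  d <- dim(l)
  if (any(d %% 2L != 0L))
    stop_invalid("every extent must be divisible by 2, got ", paste(d, collapse = "x"))
  as_label_map(unclass(l)[seq(1L, d[1], 2L), seq(1L, d[2], 2L), seq(1L, d[3], 2L)])
}

#' Zero flow on a given grid
#' @param shape integer vector (D, H, W).
#' @return a `flow` of all-zero displacements.
#' @export
zero_flow <- function(shape) {
  as_flow(array(0, c(3L, as.integer(shape))))
}
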