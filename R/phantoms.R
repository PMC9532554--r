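# Synthetic labeled phantoms and smooth random deformations.  These stand in
# for pre-aligned whole-brain scans: an outer "brain" ellipsoid with a few
# labeled interior structures of distinct intensities, deformed by smooth
# random displacement fields whose severity is calibrated against initial
# Dice rather than raw displacement magnitude.

with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Phantom generation parameters
#'
#' @param shape grid extents (D, H, W); keep divisible by `2^(levels + 1)` of
#'   the intended backbone so the two-scale cascade applies.
#' @param n_structures number of labeled interior structures (>= 1).
#' @param intensity_range intensity band (0-255 scale) across which structure
#'   mean intensities are evenly spread.
#' @param smoothing_sigma Gaussian pre-blur of the phantom (voxels); 0 keeps
#'   razor-sharp step edges.
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(32L, 32L, 32L), n_structures = 4L,
                         intensity_range = c(130, 245), smoothing_sigma = 1,
                         seed = 0L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop_invalid("shape must give 3 extents of at least 16 voxels")
  if (n_structures < 1L) stop_invalid("n_structures must be >= 1")
  structure(list(shape = shape, n_structures = as.integer(n_structures),
                 intensity_range = as.numeric(intensity_range),
                 smoothing_sigma = smoothing_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Deformation generation parameters
#'
#' @param amplitude maximum displacement magnitude in voxels (>= 0).
#' @param smoothness_sigma Gaussian smoothing scale of the random field
#'   (voxels, > 0); presets keep it >= 2 so the discrete flow composition
#'   stays close to its continuous limit.
#' @param seed RNG seed.
#' @return a `deformation_spec` list.
#' @export
deformation_spec <- function(amplitude = 4, smoothness_sigma = 2, seed = 0L) {
  if (amplitude < 0) stop_invalid("amplitude must be >= 0")
  if (smoothness_sigma <= 0) stop_invalid("smoothness_sigma must be > 0")
  structure(list(amplitude = amplitude, smoothness_sigma = smoothness_sigma,
                 seed = as.integer(seed)),
            class = "deformation_spec")
}

# Separable Gaussian blur with replicate padding.
gauss_blur3 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  d <- dim(x)
  for (ax in 1:3) {
    n <- d[ax]
    acc <- array(0, d)
    for (j in -r:r) {
      idx <- pmin(pmax(seq_len(n) + j, 1L), n)
      acc <- acc + k[j + r + 1L] * switch(ax,
        x[idx, , , drop = FALSE],
        x[, idx, , drop = FALSE],
        x[, , idx, drop = FALSE])
    }
    x <- acc
  }
  x
}

coord_arrays <- function(shape) {
  list(
    d = array(rep(seq_len(shape[1]) - 1, times = shape[2] * shape[3]), shape),
    h = array(rep(rep(seq_len(shape[2]) - 1, each = shape[1]), times = shape[3]), shape),
    w = array(rep(seq_len(shape[3]) - 1, each = shape[1] * shape[2]), shape))
}

ellipsoid_mask <- function(coords, center, semi) {
  ((coords$d - center[1]) / semi[1])^2 +
    ((coords$h - center[2]) / semi[2])^2 +
    ((coords$w - center[3]) / semi[3])^2 <= 1
}

#' Generate a labeled brain-like phantom
#'
#' One outer ellipsoidal tissue region plus `n_structures` non-overlapping
#' interior ellipsoidal structures with distinct labels 1..n and distinct
#' mean intensities, optionally Gaussian-smoothed. Deterministic in the
#' spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` and `labels`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  shape <- spec$shape
  with_seed(spec$seed, {
    coords <- coord_arrays(shape)
    center0 <- (shape - 1) / 2
    outer_semi <- 0.42 * shape
    outer <- ellipsoid_mask(coords, center0, outer_semi)
    labels <- array(0L, shape)
    intensities <- seq(spec$intensity_range[1], spec$intensity_range[2],
                       length.out = spec$n_structures)
    vol <- array(0, shape)
    vol[outer] <- 80
    rmin <- 0.055 * min(shape)
    rmax <- 0.110 * min(shape)
    for (i in seq_len(spec$n_structures)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        semi <- stats::runif(3, rmin, rmax)
        center <- center0 + (stats::runif(3, -1, 1) * (outer_semi - semi - 1.5)) *
          stats::runif(1, 0.2, 0.95)
        mask <- ellipsoid_mask(coords, center, semi)
        if (!any(mask)) next
        if (any(mask & !outer)) next
        if (any(labels[mask] != 0L)) next
        labels[mask] <- i
        vol[mask] <- intensities[i]
        placed <- TRUE
        break
      }
      if (!placed)
        stop(errorCondition(
          sprintf("could not place structure %d without overlap after 200 tries", i),
          class = c("progreg_generation_error", "error")))
    }
    vol <- gauss_blur3(vol, spec$smoothing_sigma)
    list(volume = as_volume(vol), labels = as_label_map(labels))
  })
}

#' Random smooth displacement field
#'
#' Three channels of white noise, Gaussian-smoothed at `smoothness_sigma`,
#' globally rescaled so the maximum per-voxel displacement norm equals
#' `amplitude`. Deterministic in the spec's seed.
#'
#' @param shape grid extents (D, H, W).
#' @param spec a [deformation_spec()].
#' @return a `flow`.
#' @export
random_smooth_flow <- function(shape, spec = deformation_spec()) {
  shape <- as.integer(shape)
  if (spec$amplitude == 0) return(zero_flow(shape))
  with_seed(spec$seed, {
    # Blur white noise on an extended grid and crop, so the smoothed field is
    # stationary (edge padding would otherwise inflate the variance at the
    # borders and let a boundary spike dominate the max-norm rescaling).
    r <- max(1L, ceiling(3 * spec$smoothness_sigma))
    ext <- shape + 2L * r
    keep_d <- r + seq_len(shape[1]); keep_h <- r + seq_len(shape[2])
    keep_w <- r + seq_len(shape[3])
    u <- array(0, c(3L, shape))
    for (comp in 1:3) {
      big <- gauss_blur3(array(stats::rnorm(prod(ext)), ext), spec$smoothness_sigma)
      u[comp, , , ] <- big[keep_d, keep_h, keep_w]
    }
    norms <- sqrt(colSums(matrix(u, nrow = 3)^2))
    mx <- max(norms)
    if (mx > 0) u <- u * (spec$amplitude / mx)
    as_flow(u)
  })
}

#' Generate a synthetic registration pair with known ground truth
#'
#' The fixed image is a phantom; the moving image is the fixed image warped
#' by a random smooth field `u_gt` (and its labels warped nearest-neighbour),
#' emulating the residual non-linear deformation left after global linear
#' pre-alignment. The moving volume is re-based as primary data
#' (interpolation depth 0).
#'
#' @param pspec a [phantom_spec()].
#' @param dspec a [deformation_spec()].
#' @return list with `fixed`, `fixed_labels`, `moving`, `moving_labels`, and
#'   the generating flow `u_gt`.
#' @export
make_pair <- function(pspec = phantom_spec(), dspec = deformation_spec()) {
  ph <- make_phantom(pspec)
  u_gt <- random_smooth_flow(pspec$shape, dspec)
  moving <- as_volume(unclass(warp_image(ph$volume, u_gt)))
  moving_labels <- warp_labels(ph$labels, u_gt)
  list(fixed = ph$volume, fixed_labels = ph$labels,
       moving = moving, moving_labels = moving_labels, u_gt = u_gt)
}

structure_by_size <- function(labels, which = c("smallest", "largest")) {
  which <- match.arg(which)
  ids <- label_ids(labels)
  sizes <- vapply(ids, function(l) sum(unclass(labels) == l), 0)
  ids[if (which == "smallest") which.min(sizes) else which.max(sizes)]
}

#' Calibrate deformation severity against initial Dice
#'
#' Bisects the deformation amplitude until the initial (unregistered) Dice of
#' the chosen structure falls inside `target_band`. This anchors the
#' "small"/"large" deformation presets to overlap criteria (0.6 for small
#' structures, 0.8 for large ones) rather than to raw displacement
#' magnitudes.
#'
#' @param pspec a [phantom_spec()].
#' @param target_band numeric `(lo, hi)` with `0 <= lo < hi <= 1`.
#' @param which calibrate on the `"smallest"` or `"largest"` structure.
#' @param smoothness_sigma smoothing scale of the candidate fields.
#' @param seed seed of the candidate fields.
#' @param max_amplitude upper bisection bound (voxels).
#' @return the calibrated [deformation_spec()].
#' @export
calibrate_severity <- function(pspec, target_band, which = c("smallest", "largest"),
                               smoothness_sigma = 2, seed = 0L,
                               max_amplitude = min(pspec$shape) / 4) {
  which <- match.arg(which)
  lo <- target_band[1]
  hi <- target_band[2]
  if (!(lo >= 0 && lo < hi && hi <= 1))
    stop_invalid("target_band must satisfy 0 <= lo < hi <= 1")
  ph <- make_phantom(pspec)
  lab <- structure_by_size(ph$labels, which)
  dice_at <- function(a) {
    if (a == 0) return(1)
    u <- random_smooth_flow(pspec$shape, deformation_spec(a, smoothness_sigma, seed))
    dice(warp_labels(ph$labels, u), ph$labels, lab)
  }
  if (dice_at(0) <= hi) return(deformation_spec(0, smoothness_sigma, seed))
  a_lo <- 0
  a_hi <- max_amplitude
  d_hi <- dice_at(a_hi)
  if (d_hi > hi)
    stop(errorCondition("target band unreachable within the amplitude bounds",
                        class = c("progreg_calibration_error", "error")))
  for (iter in seq_len(60L)) {
    mid <- (a_lo + a_hi) / 2
    d <- dice_at(mid)
    if (d >= lo && d <= hi)
      return(deformation_spec(mid, smoothness_sigma, seed))
    if (d < lo) a_hi <- mid else a_lo <- mid
  }
  stop(errorCondition("severity calibration did not converge",
                      class = c("progreg_calibration_error", "error")))
}

#' Deformation presets anchored to overlap criteria
#'
#' `"large"` calibrates the smallest structure's initial Dice into
#' (0.30, 0.55) — clearly below the 0.6 well-aligned criterion for small
#' structures — and `"small"` into (0.70, 0.90).
#'
#' @param pspec a [phantom_spec()].
#' @param severity `"large"` or `"small"`.
#' @param seed seed of the calibration field.
#' @return a calibrated [deformation_spec()].
#' @export
deformation_preset <- function(pspec, severity = c("large", "small"), seed = 0L) {
  severity <- match.arg(severity)
  band <- if (severity == "large") c(0.30, 0.55) else c(0.70, 0.90)
  calibrate_severity(pspec, band, which = "smallest", smoothness_sigma = 3, seed = seed)
}

#' Generate a set of registration pairs sharing one template
#'
#' All pairs share the fixed phantom (the template every moving image is
#' registered to, as in atlas-based pipelines); each pair applies an
#' independent random smooth deformation at the amplitude of the requested
#' severity preset.
#'
#' @param n number of pairs.
#' @param pspec a [phantom_spec()].
#' @param severity `"large"` or `"small"` (see [deformation_preset()]).
#' @param seed base seed; pair `i` deforms with seed `seed + 101 * i`.
#' @param amplitude optional fixed deformation amplitude (voxels); when given,
#'   the severity calibration is skipped.
#' @return list of `n` pairs as from [make_pair()].
#' @export
make_pair_set <- function(n, pspec = phantom_spec(), severity = "large", seed = 0L,
                          amplitude = NULL) {
  base <- if (is.null(amplitude))
    deformation_preset(pspec, severity, seed = seed)
  else
    deformation_spec(amplitude, 3, seed = seed)
  ph <- make_phantom(pspec)
  lapply(seq_len(n), function(i) {
    u_gt <- random_smooth_flow(pspec$shape,
                               deformation_spec(base$amplitude, base$smoothness_sigma,
                                                seed = seed + 101L * i))
    list(fixed = ph$volume, fixed_labels = ph$labels,
         moving = as_volume(unclass(warp_image(ph$volume, u_gt))),
         moving_labels = warp_labels(ph$labels, u_gt),
         u_gt = u_gt)
  })
}
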