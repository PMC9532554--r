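# Shared fixtures: small deterministic volumes, flows, and a tiny backbone
# configuration cheap enough for unit tests.

linear_volume <- function(shape, a = 1, b = 2, c = 3, d0 = -1) {
  # f(x, y, z) = a + b*x + c*y + d0*z on 0-based voxel coordinates
  co <- expand.grid(x = 0:(shape[1] - 1), y = 0:(shape[2] - 1), z = 0:(shape[3] - 1))
  as_volume(array(a + b * co$x + c * co$y + d0 * co$z, shape))
}

ramp_volume <- function(shape) linear_volume(shape, a = 0, b = 1, c = 0, d0 = 0)

constant_flow <- function(shape, v) {
  u <- array(0, c(3, shape))
  u[1, , , ] <- v[1]; u[2, , , ] <- v[2]; u[3, , , ] <- v[3]
  as_flow(u)
}

smooth_test_flow <- function(shape, amplitude = 1.5, sigma = 2, seed = 1) {
  random_smooth_flow(shape, deformation_spec(amplitude, sigma, seed))
}

tiny_backbone_config <- function() {
  backbone_config(levels = 2L, enc_channels = c(4L, 8L),
                  dec_channels = c(8L, 4L, 4L))
}

zeroed_backbone <- function(cfg = tiny_backbone_config()) {
  net <- init_backbone(cfg, seed = 0)
  net$params <- lapply(net$params, function(p)
    list(w = array(0, dim(p$w)), b = numeric(length(p$b))))
  net
}

# Small random-weight backbone producing modest nonzero flows.
jittered_backbone <- function(cfg = tiny_backbone_config(), seed = 7, head_sd = 0.05) {
  net <- init_backbone(cfg, seed = seed)
  set.seed(seed + 1)
  net$params$head$w <- array(stats::rnorm(length(net$params$head$w), sd = head_sd),
                             dim(net$params$head$w))
  net$params$head$b <- stats::rnorm(3, sd = 0.3)
  net
}
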