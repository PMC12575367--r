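# Shared fixtures: every scene is built in code at test time.

small_cfg <- function(seed = 1L, px = 1, shape = c(256L, 256L)) {
  scene_config(seed = seed, pixel_size = px, image_shape = shape)
}

quadratic_radial_spec <- function(R, eps = 0.1, n_frames = 2L) {
  field_spec("radial_profile",
             g = function(r) eps * r^2 / R,
             gprime = function(r) 2 * eps * r / R,
             n_frames = n_frames)
}

affine_spec <- function(A, n_frames = 2L) {
  field_spec("affine", affine_matrix = A, n_frames = n_frames)
}

rotation_matrix <- function(deg) {
  phi <- deg * pi / 180
  matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
}

deg <- function(x) x * pi / 180

# Rayleigh test p-value (uniformity of directions), used only as an
# independent oracle against generated walks.
rayleigh_p <- function(angles_deg) {
  n <- length(angles_deg)
  a <- angles_deg * pi / 180
  rbar <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  min(max(p, 0), 1)
}

# Synthetic grating tile with stripes along math-frame orientation phi_deg.
grating_tile <- function(phi_deg, size = 96, period = 8) {
  phi <- phi_deg * pi / 180
  x <- matrix((seq_len(size) - 0.5), size, size, byrow = TRUE)
  y <- matrix((seq_len(size) - 0.5), size, size)
  s <- -x * sin(phi) - y * cos(phi)  # normal coordinate, storage y down
  0.5 + 0.5 * cos(2 * pi * s / period)
}
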