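#' Scene configuration for a synthetic stretch-imaging experiment
#'
#' Bundles the geometry and imaging cadence shared by every synthetic
#' generator: pixel size, image shape, the position and radius of the
#' circular deformation pillar, and the frame interval. All lengths are in
#' micrometres; coordinates are Cartesian x-y with the origin at the image
#' top-left corner (pixel space has y increasing downward; angles reported
#' by the package are always converted to the mathematical, y-up
#' convention).
#'
#' @param seed Integer root seed. Identical seeds reproduce identical
#'   outputs from every generator in the package.
#' @param pixel_size Pixel size in micrometres per pixel.
#' @param image_shape Integer vector `c(rows, cols)` of the rendered images.
#' @param pillar_center Numeric `c(x, y)` centre of the deformation pillar
#'   in micrometres; defaults to the image centre.
#' @param pillar_radius Pillar radius in micrometres; defaults to 45% of the
#'   smaller image dimension so the pillar fits fully inside the frame.
#' @param frame_interval Time between frames in minutes. Bead-displacement
#'   validation imaging in the emulated study acquires one frame per minute
#'   over ten minutes; migration imaging is one frame per minute over an
#'   hour.
#'
#' @return An object of class `scene_config` (a named list).
#' @export
#' @examples
#' cfg <- scene_config(seed = 1)
#' cfg$pillar_radius
scene_config <- function(seed = 1L,
                         pixel_size = 0.65,
                         image_shape = c(512L, 512L),
                         pillar_center = NULL,
                         pillar_radius = NULL,
                         frame_interval = 1) {
  stopifnot(pixel_size > 0, length(image_shape) == 2L, all(image_shape >= 16),
            frame_interval > 0)
  extent <- rev(image_shape) * pixel_size  # (x extent, y extent) in um
  if (is.null(pillar_center)) pillar_center <- extent / 2
  if (is.null(pillar_radius)) pillar_radius <- 0.45 * min(extent)
  stopifnot(length(pillar_center) == 2L, pillar_radius > 0)
  if (pillar_center[1] - pillar_radius < 0 ||
      pillar_center[2] - pillar_radius < 0 ||
      pillar_center[1] + pillar_radius > extent[1] ||
      pillar_center[2] + pillar_radius > extent[2]) {
    stop("pillar must lie fully inside the image", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), pixel_size = pixel_size,
         image_shape = as.integer(image_shape),
         pillar_center = as.numeric(pillar_center),
         pillar_radius = as.numeric(pillar_radius),
         frame_interval = frame_interval),
    class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat("<scene_config>\n",
      sprintf("  seed: %d | pixel: %.3g um | image: %d x %d px\n",
              x$seed, x$pixel_size, x$image_shape[1], x$image_shape[2]),
      sprintf("  pillar: centre (%.1f, %.1f) um, radius %.1f um\n",
              x$pillar_center[1], x$pillar_center[2], x$pillar_radius),
      sprintf("  frame interval: %g min\n", x$frame_interval), sep = "")
  invisible(x)
}

# Derive a reproducible child seed from a root seed and a component label,
# so each generator consumes an independent stream. Kept below 2^31 - 1.
child_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Radial micropattern specification
#'
#' Describes a radial arrangement of alternating ridges and grooves around a
#' centre: stripes run along the radial direction, so the local pattern
#' orientation at any point equals the polar angle of that point (modulo
#' 180 degrees). Because the arc width of an angular stripe grows linearly
#' with radius, the pattern is subdivided along r: whenever the ridge arc
#' width would exceed `ridge_width_max`, the number of angular stripes is
#' doubled, which keeps every stripe width inside
#' `[groove_width_min, ridge_width_max]` provided the max/min ratio is at
#' least 2.
#'
#' @param center Numeric `c(x, y)` pattern centre in micrometres.
#' @param r_inner,r_outer Inner and outer radii of the patterned annulus
#'   (micrometres).
#' @param ridge_width_max Maximum stripe width in micrometres (default 5).
#' @param groove_width_min Minimum stripe width in micrometres (default 2).
#' @return An object of class `pattern_spec`.
#' @export
pattern_spec <- function(center, r_inner, r_outer,
                         ridge_width_max = 5, groove_width_min = 2) {
  stopifnot(r_inner > 0, r_inner < r_outer,
            groove_width_min > 0, ridge_width_max > groove_width_min)
  if (ridge_width_max / groove_width_min < 2) {
    stop("width bounds infeasible: doubling subdivision needs max/min >= 2",
         call. = FALSE)
  }
  structure(
    list(center = as.numeric(center), r_inner = r_inner, r_outer = r_outer,
         ridge_width_max = ridge_width_max,
         groove_width_min = groove_width_min),
    class = "pattern_spec")
}

#' Prescribed planar displacement field
#'
#' Ground-truth displacement fields come in two kinds. `"affine"` applies
#' `u(p) = (A - I) (p - center)` for a constant 2x2 matrix `A`, so the
#' deformation gradient is `A` everywhere. `"radial_profile"` applies a
#' purely radial displacement `u(p) = g(r) r_hat` about the centre, for a
#' monotone non-decreasing profile `g` with `g(0) = 0`; its deformation
#' gradient in the local polar frame is `diag(1 + g'(r), 1 + g(r)/r)`. The
#' field is ramped linearly across frames from 0 at frame 0 to its full
#' value at the last frame, emulating a pressure ramp followed by hold.
#'
#' @param kind `"affine"` or `"radial_profile"`.
#' @param affine_matrix 2x2 matrix `A` (affine kind).
#' @param g,gprime Profile function `g(r)` (micrometres) and its derivative;
#'   if `gprime` is omitted a central finite difference is used.
#' @param n_frames Number of frames over which the field is ramped
#'   (including the undeformed frame 0).
#' @param ramp Optional numeric vector of per-frame scalings in `[0, 1]` of
#'   length `n_frames`; defaults to a linear ramp `seq(0, 1)`.
#' @return An object of class `field_spec`.
#' @export
#' @examples
#' fs <- field_spec("affine", affine_matrix = diag(c(1.1, 1.1)), n_frames = 11)
#' fr <- field_spec("radial_profile", g = function(r) 0.1 * r^2 / 150,
#'                  gprime = function(r) 0.2 * r / 150, n_frames = 11)
field_spec <- function(kind = c("affine", "radial_profile"),
                       affine_matrix = NULL, g = NULL, gprime = NULL,
                       n_frames = 11L, ramp = NULL) {
  kind <- match.arg(kind)
  stopifnot(n_frames >= 2)
  if (kind == "affine") {
    stopifnot(is.matrix(affine_matrix), all(dim(affine_matrix) == 2L))
  } else {
    stopifnot(is.function(g))
    if (abs(g(0)) > 1e-9) stop("radial profile must satisfy g(0) = 0",
                               call. = FALSE)
    if (is.null(gprime)) {
      gfun <- g
      gprime <- function(r) {
        h <- pmax(1e-4, 1e-6 * pmax(r, 1))
        (gfun(r + h) - gfun(pmax(r - h, 0))) / (h + pmin(r, h))
      }
    }
  }
  if (is.null(ramp)) ramp <- seq(0, 1, length.out = n_frames)
  stopifnot(length(ramp) == n_frames, all(ramp >= 0), all(ramp <= 1))
  structure(
    list(kind = kind, affine_matrix = affine_matrix, g = g, gprime = gprime,
         n_frames = as.integer(n_frames), ramp = ramp),
    class = "field_spec")
}

# Per-condition presets for the migration generator. The ordering encodes
# the study's qualitative findings: deformation raises turning-angle
# concentration (persistence), the patterned + deformed condition is the
# most persistent and has the highest and narrowest speed distribution, and
# undeformed conditions share a collective drift direction instead.
migration_presets <- function() {
  list(
    flat_undeformed = list(
      speed_lognormal = c(meanlog = log(0.40), sdlog = 0.50),
      turning_concentration = 0.3, drift = 30, drift_weight = 0.25,
      radial_bias = 0),
    patterned_undeformed = list(
      speed_lognormal = c(meanlog = log(0.45), sdlog = 0.50),
      turning_concentration = 0.5, drift = 30, drift_weight = 0.25,
      radial_bias = 0),
    flat_deformed = list(
      speed_lognormal = c(meanlog = log(0.55), sdlog = 0.40),
      turning_concentration = 1.5, drift = NULL, drift_weight = 0,
      radial_bias = 0.15),
    patterned_deformed = list(
      speed_lognormal = c(meanlog = log(0.70), sdlog = 0.30),
      turning_concentration = 2.5, drift = NULL, drift_weight = 0,
      radial_bias = 0.30))
}

#' Migration-condition specification
#'
#' Parameterises the persistent-random-walk generator for one of the four
#' experimental conditions (flat/patterned crossed with
#' undeformed/deformed). Per-step speeds are lognormal; turning angles are
#' von Mises about the previous heading with concentration `kappa`
#' (`kappa = 0` gives uniform turning angles, i.e. an uncorrelated walk).
#' Undeformed conditions optionally share a collective drift direction;
#' deformed conditions are biased toward the local radial direction of the
#' stretch. The built-in presets order the conditions as observed in the
#' emulated study: deformed > undeformed in persistence, with
#' `patterned_deformed` the most persistent and fastest/narrowest in speed.
#'
#' @param condition One of `"flat_undeformed"`, `"patterned_undeformed"`,
#'   `"flat_deformed"`, `"patterned_deformed"`.
#' @param speed_lognormal Named numeric `c(meanlog, sdlog)` of per-step
#'   speeds in micrometres per minute.
#' @param turning_concentration von Mises concentration `kappa >= 0` of
#'   turning angles.
#' @param drift Optional common drift direction in degrees (undeformed
#'   collective motion), or `NULL`.
#' @param drift_weight Fraction in `[0, 1]` by which each step relaxes the
#'   heading toward `drift`.
#' @param radial_bias Fraction in `[0, 1]` by which each step relaxes the
#'   heading toward the local outward radial direction.
#' @return An object of class `migration_spec`.
#' @export
#' @examples
#' migration_spec("patterned_deformed")
migration_spec <- function(condition = c("flat_undeformed",
                                         "patterned_undeformed",
                                         "flat_deformed",
                                         "patterned_deformed"),
                           speed_lognormal = NULL,
                           turning_concentration = NULL,
                           drift = NULL, drift_weight = NULL,
                           radial_bias = NULL) {
  condition <- match.arg(condition)
  preset <- migration_presets()[[condition]]
  spec <- list(
    condition = condition,
    speed_lognormal = speed_lognormal %||% preset$speed_lognormal,
    turning_concentration =
      turning_concentration %||% preset$turning_concentration,
    drift = if (is.null(drift)) preset$drift else drift,
    drift_weight = drift_weight %||% preset$drift_weight,
    radial_bias = radial_bias %||% preset$radial_bias)
  stopifnot(spec$turning_concentration >= 0,
            spec$radial_bias >= 0, spec$radial_bias <= 1,
            spec$drift_weight >= 0, spec$drift_weight <= 1)
  structure(spec, class = "migration_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
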