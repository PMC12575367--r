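# Angle conventions used throughout the package:
#   * degrees everywhere in user-facing interfaces,
#   * counter-clockwise positive, measured from the +x axis,
#   * directional data (headings, turning angles) wrapped to (-180, 180],
#   * axial data (orientations, defined modulo 180) wrapped to [0, 180),
#   * axial differences wrapped to [-90, 90).
# Pixel space has y increasing downward; a single y-flip is applied wherever
# an angle is derived from pixel coordinates so reported angles follow the
# mathematical convention.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap directional angles to (-180, 180]
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector wrapped to the half-open interval (-180, 180].
#' @export
#' @examples
#' wrap_directional(c(190, -190, 180, -180, 540))
wrap_directional <- function(x) {
  y <- x %% 360
  ifelse(y > 180, y - 360, ifelse(y <= -180, y + 360, y))
}

#' Wrap axial orientations to [0, 180)
#'
#' Axial data are defined modulo 180 degrees: an object oriented at 10
#' degrees is indistinguishable from one at 190 degrees.
#'
#' @param x Numeric vector of orientations in degrees.
#' @return Numeric vector in `[0, 180)`.
#' @export
wrap_axial <- function(x) x %% 180

#' Wrap an axial difference to [-90, 90)
#'
#' The signed difference between two orientations (each modulo 180) lives on
#' `[-90, 90)`. This is the wrap used for the angular-alignment statistic
#' gamma, and the only wrap under which perfectly aligned axial data produce
#' differences concentrated at zero.
#'
#' @param x Numeric vector of orientation differences in degrees.
#' @return Numeric vector in `[-90, 90)`.
#' @export
#' @examples
#' wrap_axial_diff(2 - 178)  # 4, not -176
wrap_axial_diff <- function(x) {
  y <- x %% 180
  ifelse(y >= 90, y - 180, y)
}

#' Circular mean of directional angles
#'
#' @param x Angles in degrees (period 360).
#' @return Mean direction in degrees in (-180, 180], or `NA` if the mean
#'   resultant length is numerically zero.
#' @export
circular_mean <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  s <- mean(sin(deg2rad(x)))
  c <- mean(cos(deg2rad(x)))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  wrap_directional(rad2deg(atan2(s, c)))
}

#' Mean resultant length of directional angles
#'
#' Equals 1 for identical directions and tends to 0 for uniformly dispersed
#' directions; used as the persistence index of turning-angle sets.
#'
#' @param x Angles in degrees (period 360).
#' @return Scalar in `[0, 1]`.
#' @export
resultant_length <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean(sin(deg2rad(x)))^2 + mean(cos(deg2rad(x)))^2)
}

#' Axial (mod-180) circular mean
#'
#' Uses the double-angle device: orientations are doubled, averaged on the
#' circle, and halved, which is invariant to the 180-degree ambiguity.
#'
#' @param x Orientations in degrees (period 180).
#' @return Mean orientation in `[0, 180)`, or `NA` when the doubled
#'   resultant length vanishes (isotropic sample).
#' @export
axial_mean <- function(x) {
  m2 <- circular_mean(wrap_directional(2 * x))
  if (is.na(m2)) return(NA_real_)
  wrap_axial(m2 / 2)
}

#' Axial resultant length
#'
#' Resultant length of doubled orientations; 1 for perfectly parallel axial
#' data, near 0 for isotropic data.
#'
#' @param x Orientations in degrees (period 180).
#' @return Scalar in `[0, 1]`.
#' @export
axial_resultant_length <- function(x) resultant_length(2 * x)

#' Axial circular standard deviation
#'
#' Mardia's circular standard deviation applied on the doubled scale and
#' mapped back, in degrees: `sqrt(-2 log R2) / 2` with `R2` the doubled
#' resultant length. Approximates the wrapped-normal sigma for moderate
#' dispersion.
#'
#' @param x Orientations in degrees (period 180).
#' @return Dispersion in degrees.
#' @export
axial_sd <- function(x) {
  r2 <- axial_resultant_length(x)
  if (is.na(r2) || r2 <= 0) return(NA_real_)
  rad2deg(sqrt(-2 * log(r2))) / 2
}

# von Mises sampler (Best & Fisher 1979 rejection method).
# mu in degrees, kappa >= 0; returns degrees in (-180, 180].
# kappa = 0 falls back to the uniform law on the circle.
rvonmises_deg <- function(n, mu = 0, kappa = 0) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(wrap_directional(stats::runif(n, -180, 180)))
  if (kappa > 1e6) return(rep(wrap_directional(mu), n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      theta <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[(got + 1L):(got + k)] <- theta
      got <- got + k
    }
  }
  wrap_directional(rad2deg(out) + mu)
}
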