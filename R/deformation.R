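# Reconstruction of the planar displacement field and the local deformation
# gradient F from tracked fiducial beads, with polar decomposition into
# rotation and principal stretches. F follows the continuum-mechanics
# convention F = dx/dX, estimated with respect to the reference
# (undeformed) frame; only the in-plane 2x2 block is considered.

#' Displacement field between two frames of a track table
#'
#' Uses only tracks present in both the reference and the target frame;
#' each retained track contributes its reference position and the
#' displacement to the target frame.
#'
#' @param tracks Tibble with `track_id`, `frame`, `x`, `y` (micrometres).
#' @param frame_ref,frame_target Frame indices (reference strictly first in
#'   time or equal for a null field).
#' @return A `displacement_field` tibble: `x0`, `y0`, `ux`, `uy`
#'   (micrometres), with attributes `frame_ref`, `frame_target`,
#'   `n_dropped` (tracks missing one of the frames).
#' @export
#' @examples
#' tr <- tibble::tibble(track_id = rep(1:3, each = 2),
#'                      frame = rep(0:1, 3),
#'                      x = c(0, 1, 10, 12, 20, 23), y = rep(0, 6))
#' displacement_field(tr, 0, 1)
displacement_field <- function(tracks, frame_ref, frame_target) {
  stopifnot(frame_ref <= frame_target)
  a <- tracks[tracks$frame == frame_ref, c("track_id", "x", "y")]
  b <- tracks[tracks$frame == frame_target, c("track_id", "x", "y")]
  m <- dplyr::inner_join(a, b, by = "track_id", suffix = c("0", "1"))
  n_dropped <- length(unique(c(a$track_id, b$track_id))) - nrow(m)
  if (nrow(m) < 3L) {
    stop("fewer than 3 tracks span both frames: field underdetermined",
         call. = FALSE)
  }
  out <- tibble::tibble(track_id = m$track_id, x0 = m$x0, y0 = m$y0,
                        ux = m$x1 - m$x0, uy = m$y1 - m$y0)
  attr(out, "frame_ref") <- frame_ref
  attr(out, "frame_target") <- frame_target
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("displacement_field", class(out))
  out
}

# Square grid of nodes clipped to a disc. Built from centre-relative
# offsets so translated scenes produce exactly corresponding nodes.
disc_grid <- function(center, radius, spacing) {
  rel <- seq(-radius, radius, by = spacing)
  g <- expand.grid(x = rel, y = rel)
  g <- g[g$x^2 + g$y^2 <= radius^2, ]
  tibble::tibble(x = g$x + center[1], y = g$y + center[2])
}

#' Estimate the local deformation-gradient map
#'
#' At each node of a square grid clipped to the pillar disc, fits the local
#' affine model `u_i = a + (F - I)(p_i - node)` to the displacement
#' observations by weighted least squares with a Gaussian kernel (bandwidth
#' `neighborhood_radius / 2`). Nodes whose neighbourhood holds fewer than 3
#' beads, or whose support is (near-)collinear, are masked rather than
#' extrapolated. Least squares is exact when the generating field is
#' affine, whatever the bead layout, so long as the support is
#' non-degenerate.
#'
#' @param dispfield A [displacement_field()] tibble.
#' @param center,radius Pillar centre (micrometres) and radius defining the
#'   analysis disc.
#' @param grid_spacing Node spacing in micrometres; default `radius / 20`.
#' @param neighborhood_radius Radius of the estimation neighbourhood
#'   (micrometres); default `3 * grid_spacing`.
#' @param min_spread Minimum weighted standard deviation of the support
#'   positions along their least-spread direction, as a fraction of
#'   `neighborhood_radius` (default 0.15). Nodes below it have too little
#'   leverage for a stable gradient and are masked.
#' @return A `deformation_map` tibble with one row per node: `x`, `y`,
#'   `F_xx`, `F_xy`, `F_yx`, `F_yy`, `n_support`, `rms_residual`
#'   (micrometres), `lambda1`, `lambda2` (principal stretches,
#'   `lambda1 >= lambda2`), `rotation_deg`, `max_shear`, `det_F`; masked
#'   nodes carry `NA` in the estimated columns.
#' @export
estimate_F <- function(dispfield, center, radius,
                       grid_spacing = radius / 20,
                       neighborhood_radius = 3 * grid_spacing,
                       min_spread = 0.15) {
  stopifnot(nrow(dispfield) >= 3, grid_spacing > 0, neighborhood_radius > 0)
  nodes <- disc_grid(center, radius, grid_spacing)
  h <- neighborhood_radius / 2
  px <- dispfield$x0; py <- dispfield$y0
  ux <- dispfield$ux; uy <- dispfield$uy
  n_nodes <- nrow(nodes)
  Fc <- matrix(NA_real_, n_nodes, 4,
               dimnames = list(NULL, c("F_xx", "F_xy", "F_yx", "F_yy")))
  nsup <- integer(n_nodes); resid <- rep(NA_real_, n_nodes)
  for (i in seq_len(n_nodes)) {
    dx <- px - nodes$x[i]; dy <- py - nodes$y[i]
    d2 <- dx^2 + dy^2
    sel <- d2 <= neighborhood_radius^2
    nsup[i] <- sum(sel)
    if (nsup[i] < 3L) next
    w <- exp(-d2[sel] / (2 * h^2))
    # weighted spread of the support along its least-spread axis: guards
    # against near-collinear configurations with unstable leverage
    wn <- w / sum(w)
    mx <- sum(wn * dx[sel]); my <- sum(wn * dy[sel])
    cxx <- sum(wn * (dx[sel] - mx)^2); cyy <- sum(wn * (dy[sel] - my)^2)
    cxy <- sum(wn * (dx[sel] - mx) * (dy[sel] - my))
    min_eig <- (cxx + cyy) / 2 - sqrt(((cxx - cyy) / 2)^2 + cxy^2)
    if (sqrt(max(min_eig, 0)) < min_spread * neighborhood_radius) next
    X <- cbind(1, dx[sel], dy[sel])
    XtW <- t(X * w)
    M <- XtW %*% X
    # collinear support leaves the normal matrix rank-deficient
    if (rcond(M) < 1e-10) next
    Minv <- solve(M)
    bx <- Minv %*% (XtW %*% ux[sel])
    by <- Minv %*% (XtW %*% uy[sel])
    G <- matrix(c(bx[2], bx[3], by[2], by[3]), 2, 2, byrow = TRUE)
    Fi <- G + diag(2)
    Fc[i, ] <- c(Fi[1, 1], Fi[1, 2], Fi[2, 1], Fi[2, 2])
    pred_x <- X %*% bx; pred_y <- X %*% by
    resid[i] <- sqrt(sum(w * ((ux[sel] - pred_x)^2 + (uy[sel] - pred_y)^2)) /
                       (2 * sum(w)))
  }
  out <- dplyr::bind_cols(nodes, tibble::as_tibble(Fc),
                          tibble::tibble(n_support = nsup,
                                         rms_residual = resid))
  dec <- purrr::pmap(out[, c("F_xx", "F_xy", "F_yx", "F_yy")],
                     function(F_xx, F_xy, F_yx, F_yy) {
                       if (is.na(F_xx)) {
                         return(list(lambda1 = NA_real_, lambda2 = NA_real_,
                                     rotation_deg = NA_real_,
                                     max_shear = NA_real_, det_F = NA_real_))
                       }
                       d <- decompose_F(matrix(c(F_xx, F_xy, F_yx, F_yy),
                                               2, 2, byrow = TRUE))
                       list(lambda1 = d$principal_stretches[1],
                            lambda2 = d$principal_stretches[2],
                            rotation_deg = d$rotation_deg,
                            max_shear = d$max_shear, det_F = d$det_F)
                     })
  out <- dplyr::bind_cols(out, dplyr::bind_rows(dec))
  attr(out, "center") <- center
  attr(out, "radius") <- radius
  attr(out, "grid_spacing") <- grid_spacing
  attr(out, "neighborhood_radius") <- neighborhood_radius
  class(out) <- c("deformation_map", class(out))
  out
}

#' Polar decomposition of a 2x2 deformation gradient
#'
#' Right polar decomposition `F = R U` with `R` a proper rotation and `U`
#' symmetric positive-definite, computed from the SVD. Reports the rotation
#' angle, the ordered principal stretches, the maximum shear
#' `(lambda1 - lambda2) / 2`, the equibiaxiality index `lambda2 / lambda1`
#' and the largest off-diagonal magnitude of `F` itself.
#'
#' The rotation angle is that of the matrix `R` in the coordinate frame `F`
#' is expressed in (`atan2(R[2,1], R[1,1])`). When `F` was estimated from
#' image-storage coordinates (y down), a positive angle is a clockwise
#' rotation in the mathematical y-up frame; the magnitude is unchanged.
#'
#' @param F A 2x2 matrix with `det(F) > 0` (a non-physical determinant is
#'   flagged, not silently decomposed).
#' @return A list of class `stretch_decomposition`: `rotation_deg`,
#'   `principal_stretches` (`lambda1 >= lambda2`), `max_shear`,
#'   `equibiaxiality`, `offdiag_norm`, `det_F`, `R`, `U`, `physical`.
#' @export
#' @examples
#' decompose_F(diag(c(1.2, 1.05)))$max_shear  # 0.075
decompose_F <- function(F) {
  stopifnot(is.matrix(F), all(dim(F) == 2L))
  detF <- det(F)
  physical <- detF > 0
  if (!physical) {
    warning("det(F) <= 0: non-physical deformation gradient")
  }
  s <- svd(F)
  # force a proper rotation (det(R) = +1)
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, d))
  R <- s$u %*% D %*% t(s$v)
  U <- s$v %*% D %*% diag(s$d) %*% t(s$v)
  U <- (U + t(U)) / 2
  lam <- sort(c(s$d[1], d * s$d[2]), decreasing = TRUE)
  structure(
    list(rotation_deg = rad2deg(atan2(R[2, 1], R[1, 1])),
         principal_stretches = lam,
         max_shear = (lam[1] - lam[2]) / 2,
         equibiaxiality = lam[2] / lam[1],
         offdiag_norm = max(abs(F[1, 2]), abs(F[2, 1])),
         det_F = detF, R = R, U = U, physical = physical),
    class = "stretch_decomposition")
}

#' @export
print.stretch_decomposition <- function(x, ...) {
  cat(sprintf(
    "<stretch_decomposition> rotation %.3f deg | stretches %.4f / %.4f | max shear %.4f\n",
    x$rotation_deg, x$principal_stretches[1], x$principal_stretches[2],
    x$max_shear))
  invisible(x)
}

#' Interpolate the displacement magnitude on a grid
#'
#' Inverse-distance-weighted interpolation of `|u|` at square grid nodes,
#' masked (set to `NA`) outside the convex hull of the observed beads.
#'
#' @param dispfield A [displacement_field()] tibble.
#' @param grid_spacing Node spacing in micrometres.
#' @param power Inverse-distance weighting exponent (default 2).
#' @return A tibble `x`, `y`, `magnitude` (`NA` outside the bead hull),
#'   `ux`, `uy` (interpolated components for arrow rendering).
#' @export
displacement_map <- function(dispfield, grid_spacing, power = 2) {
  stopifnot(grid_spacing > 0, nrow(dispfield) >= 3)
  xr <- range(dispfield$x0); yr <- range(dispfield$y0)
  ax <- seq(xr[1], xr[2], by = grid_spacing)
  ay <- seq(yr[1], yr[2], by = grid_spacing)
  g <- tibble::as_tibble(expand.grid(x = ax, y = ay))
  hull <- grDevices::chull(dispfield$x0, dispfield$y0)
  bnd <- list(x = dispfield$x0[hull], y = dispfield$y0[hull])
  inside <- mgcv::in.out(cbind(c(bnd$x, bnd$x[1]), c(bnd$y, bnd$y[1])),
                         cbind(g$x, g$y))
  mag <- rep(NA_real_, nrow(g)); gux <- mag; guy <- mag
  um <- sqrt(dispfield$ux^2 + dispfield$uy^2)
  for (i in which(inside)) {
    d2 <- (dispfield$x0 - g$x[i])^2 + (dispfield$y0 - g$y[i])^2
    j <- which(d2 < 1e-16)
    if (length(j)) {
      mag[i] <- um[j[1]]; gux[i] <- dispfield$ux[j[1]]
      guy[i] <- dispfield$uy[j[1]]
    } else {
      w <- 1 / d2^(power / 2)
      w <- w / sum(w)
      mag[i] <- sum(w * um)
      gux[i] <- sum(w * dispfield$ux)
      guy[i] <- sum(w * dispfield$uy)
    }
  }
  g$magnitude <- mag; g$ux <- gux; g$uy <- guy
  class(g) <- c("displacement_magnitude_map", class(g))
  g
}

#' Radial strain profile in annular bands
#'
#' Averages the nodal mean normal strain, `(F_xx + F_yy) / 2 - 1`, within
#' equal-width annular bands over the pillar. For rotation-free fields this
#' equals the mean principal stretch minus one, `mean(lambda1, lambda2) -
#' 1`; unlike the singular-value form it is linear in the estimated `F`, so
#' localisation noise does not bias it upward. Bands with no valid nodes
#' are reported as missing.
#'
#' @param fmap A `deformation_map` from [estimate_F()].
#' @param center Pillar centre; defaults to the map's centre attribute.
#' @param n_bands Number of equal-width annular bands (default 3).
#' @param dispfield Optional [displacement_field()] used to add per-band
#'   mean displacement magnitudes.
#' @return A tibble with one row per band: `band`, `r_lo`, `r_hi`,
#'   `mean_strain`, `sd_strain`, `n_nodes`, and (when `dispfield` is given)
#'   `mean_disp`.
#' @export
radial_strain_profile <- function(fmap, center = attr(fmap, "center"),
                                  n_bands = 3,
                                  dispfield = NULL) {
  radius <- attr(fmap, "radius")
  stopifnot(!is.null(center), !is.null(radius), n_bands >= 1)
  edges <- seq(0, radius, length.out = n_bands + 1L)
  r <- sqrt((fmap$x - center[1])^2 + (fmap$y - center[2])^2)
  strain <- (fmap$F_xx + fmap$F_yy) / 2 - 1
  band <- pmin(findInterval(r, edges, rightmost.closed = TRUE), n_bands)
  out <- tibble::tibble(band = seq_len(n_bands),
                        r_lo = edges[-(n_bands + 1L)], r_hi = edges[-1])
  st <- vapply(seq_len(n_bands), function(b) {
    v <- strain[band == b & !is.na(strain)]
    c(mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1) stats::sd(v) else NA_real_,
      n = length(v))
  }, numeric(3))
  out$mean_strain <- st["mean", ]
  out$sd_strain <- st["sd", ]
  out$n_nodes <- as.integer(st["n", ])
  if (!is.null(dispfield)) {
    rb <- sqrt((dispfield$x0 - center[1])^2 + (dispfield$y0 - center[2])^2)
    bb <- pmin(findInterval(rb, edges, rightmost.closed = TRUE), n_bands)
    um <- sqrt(dispfield$ux^2 + dispfield$uy^2)
    out$mean_disp <- vapply(seq_len(n_bands), function(b) {
      v <- um[bb == b]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  }
  out
}
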