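# Synthetic-scene generators. Every input the analysis chain consumes can
# be produced here with known ground truth: the radial ridge/groove pattern,
# prescribed displacement fields, advected fiducial beads, oriented cell
# populations, persistent-random-walk trajectories and rendered image
# stacks.

# Pixel-centre coordinate grids in micrometres (x right, y down in storage;
# the y-flip to the mathematical convention happens where angles are made).
pixel_grid_um <- function(cfg) {
  rows <- cfg$image_shape[1]; cols <- cfg$image_shape[2]
  list(x = (seq_len(cols) - 0.5) * cfg$pixel_size,
       y = (seq_len(rows) - 0.5) * cfg$pixel_size)
}

# Number of angular stripes (ridges + grooves) per subdivision ring and the
# ring edges. Stripes double whenever the ridge arc width would exceed
# ridge_width_max, keeping widths in [groove_width_min, ridge_width_max].
pattern_rings <- function(spec) {
  m0 <- 2 * ceiling(pi * spec$r_inner / spec$ridge_width_max)
  w_inner <- 2 * pi * spec$r_inner / m0
  if (w_inner < spec$groove_width_min) {
    stop("width bounds infeasible at r_inner: stripes would be narrower ",
         "than groove_width_min", call. = FALSE)
  }
  edges <- spec$r_inner
  m <- m0
  counts <- integer(0)
  repeat {
    r_max_k <- spec$ridge_width_max * m / (2 * pi)
    counts <- c(counts, m)
    if (r_max_k >= spec$r_outer) {
      edges <- c(edges, spec$r_outer)
      break
    }
    edges <- c(edges, r_max_k)
    m <- 2L * m
  }
  list(m0 = m0, edges = edges, counts = counts)
}

# Vectorised ridge membership and local orientation for arbitrary points.
pattern_eval <- function(spec, x, y) {
  dx <- x - spec$center[1]
  dy_math <- -(y - spec$center[2])  # y-flip: storage y grows downward
  r <- sqrt(dx^2 + dy_math^2)
  theta <- (rad2deg(atan2(dy_math, dx))) %% 360
  rings <- pattern_rings(spec)
  inside <- r >= spec$r_inner & r <= spec$r_outer
  ring_idx <- findInterval(r, rings$edges, rightmost.closed = TRUE)
  ring_idx[!inside] <- NA_integer_
  m <- rings$counts[ring_idx]
  stripe <- floor(theta / (360 / m))
  ridge <- inside & (stripe %% 2 == 0)
  ridge[!inside] <- NA
  orientation <- ifelse(inside, wrap_axial(theta), NA_real_)
  tibble::tibble(r = r, theta = theta, inside = inside,
                 ridge = as.logical(ridge), orientation = orientation)
}

#' Rasterise a radial ridge/groove micropattern
#'
#' Builds the binary ridge mask and the local orientation field of a radial
#' micropattern on the pixel grid of a scene. Stripes run radially, so the
#' orientation at a point is its polar angle about the pattern centre
#' reduced modulo 180 degrees; pixels outside the patterned annulus carry
#' `NA`.
#'
#' @param spec A [pattern_spec()].
#' @param cfg A [scene_config()].
#' @return A list of class `radial_pattern` with elements `mask` (logical
#'   matrix, `NA` outside the annulus), `orientation` (degrees, axial),
#'   `rings` (subdivision radii and stripe counts), `spec` and `cfg`.
#' @export
#' @examples
#' cfg <- scene_config(seed = 1, image_shape = c(128, 128), pixel_size = 1)
#' pat <- make_pattern(pattern_spec(cfg$pillar_center, 10, 50), cfg)
#' mean(pat$mask, na.rm = TRUE)  # ridges cover half of the annulus
make_pattern <- function(spec, cfg) {
  stopifnot(inherits(spec, "pattern_spec"), inherits(cfg, "scene_config"))
  g <- pixel_grid_um(cfg)
  rows <- cfg$image_shape[1]; cols <- cfg$image_shape[2]
  xg <- matrix(g$x, nrow = rows, ncol = cols, byrow = TRUE)
  yg <- matrix(g$y, nrow = rows, ncol = cols)
  ev <- pattern_eval(spec, as.vector(xg), as.vector(yg))
  structure(
    list(mask = matrix(ev$ridge, nrow = rows),
         orientation = matrix(ev$orientation, nrow = rows),
         rings = pattern_rings(spec), spec = spec, cfg = cfg),
    class = "radial_pattern")
}

#' Exact pattern orientation at arbitrary points
#'
#' @param spec A [pattern_spec()] (or a `radial_pattern`, whose spec is
#'   used).
#' @param x,y Point coordinates in micrometres (storage convention, y down).
#' @return Orientations in degrees in `[0, 180)`; `NA` outside the annulus.
#' @export
pattern_orientation_at <- function(spec, x, y) {
  if (inherits(spec, "radial_pattern")) spec <- spec$spec
  pattern_eval(spec, x, y)$orientation
}

#' Instantiate a prescribed displacement field for a scene
#'
#' Binds a [field_spec()] to a scene, returning an object whose displacement
#' and ground-truth deformation gradient can be evaluated at any point and
#' frame. The field is centred on the pillar. For the radial-profile kind
#' the full-ramp deformation gradient at radius `r` is
#' `diag(1 + g'(r), 1 + g(r)/r)` in the local polar frame (the `r = 0`
#' singularity of `g(r)/r` is replaced by its limit `g'(0)`); at a ramp
#' scaling `s` the displacement is `s * u` and hence `F_s = I + s (F - I)`.
#'
#' @param spec A [field_spec()].
#' @param cfg A [scene_config()].
#' @return An object of class `scene_field`.
#' @export
generate_field <- function(spec, cfg) {
  stopifnot(inherits(spec, "field_spec"), inherits(cfg, "scene_config"))
  structure(list(spec = spec, cfg = cfg, center = cfg$pillar_center),
            class = "scene_field")
}

ramp_at <- function(field, frame) {
  if (is.null(frame)) return(1)
  stopifnot(frame >= 0, frame <= field$spec$n_frames - 1L)
  field$spec$ramp[frame + 1L]
}

#' Evaluate a scene field's displacement
#'
#' @param field A `scene_field` from [generate_field()].
#' @param xy Two-column matrix (or length-2 vector) of positions in
#'   micrometres.
#' @param frame Frame index (0-based) selecting the ramp scaling; `NULL`
#'   (default) evaluates the fully ramped field.
#' @return Two-column matrix of displacements `(ux, uy)` in micrometres.
#' @export
#' @examples
#' cfg <- scene_config(seed = 1)
#' f <- generate_field(field_spec("affine", affine_matrix = diag(c(1.1, 1.1))), cfg)
#' field_displacement(f, cfg$pillar_center + c(10, 0))  # (1, 0)
field_displacement <- function(field, xy, frame = NULL) {
  xy <- rbind(xy)
  s <- ramp_at(field, frame)
  d <- sweep(xy, 2, field$center)
  if (field$spec$kind == "affine") {
    u <- d %*% t(field$spec$affine_matrix - diag(2))
  } else {
    r <- sqrt(rowSums(d^2))
    gr <- field$spec$g(r)
    scale <- ifelse(r < 1e-12, field$spec$gprime(0), gr / pmax(r, 1e-12))
    u <- d * scale
  }
  s * u
}

#' Ground-truth deformation gradient of a scene field
#'
#' @inheritParams field_displacement
#' @return A list of 2x2 matrices, one per row of `xy`, each the analytic
#'   deformation gradient in Cartesian (storage) coordinates.
#' @export
field_F <- function(field, xy, frame = NULL) {
  xy <- rbind(xy)
  s <- ramp_at(field, frame)
  d <- sweep(xy, 2, field$center)
  n <- nrow(xy)
  out <- vector("list", n)
  if (field$spec$kind == "affine") {
    Fs <- diag(2) + s * (field$spec$affine_matrix - diag(2))
    for (i in seq_len(n)) out[[i]] <- Fs
    return(out)
  }
  r <- sqrt(rowSums(d^2))
  for (i in seq_len(n)) {
    if (r[i] < 1e-12) {
      lam <- 1 + field$spec$gprime(0)
      Ffull <- diag(c(lam, lam))
    } else {
      lr <- 1 + field$spec$gprime(r[i])       # radial stretch
      lt <- 1 + field$spec$g(r[i]) / r[i]     # hoop stretch
      ct <- d[i, 1] / r[i]; st <- d[i, 2] / r[i]
      Q <- matrix(c(ct, st, -st, ct), 2, 2)   # polar frame in storage coords
      Ffull <- Q %*% diag(c(lr, lt)) %*% t(Q)
    }
    out[[i]] <- diag(2) + s * (Ffull - diag(2))
  }
  out
}

# Uniform points in a disc / annulus (area-uniform).
runif_disc <- function(n, center, r_max, r_min = 0) {
  r <- sqrt(stats::runif(n, r_min^2, r_max^2))
  a <- stats::runif(n, 0, 2 * pi)
  cbind(x = center[1] + r * cos(a), y = center[2] + r * sin(a))
}

#' Simulate fiducial bead tracks under a prescribed field
#'
#' Beads are advected by the ramped displacement field evaluated at their
#' reference positions (Lagrangian advection), with i.i.d. Gaussian
#' localisation noise added to every frame. The noiseless ground-truth
#' positions are retained as the `truth` attribute. Beads are embedded
#' throughout the imaged membrane, so by default their reference positions
#' are uniform over the whole image; `region = "pillar"` restricts them to
#' the pillar disc.
#'
#' @param n_beads Number of beads.
#' @param field A `scene_field` from [generate_field()].
#' @param noise_sd Localisation noise standard deviation in micrometres
#'   (per coordinate, per frame).
#' @param cfg A [scene_config()].
#' @param region `"image"` (uniform over the image rectangle, the default)
#'   or `"pillar"` (uniform over the pillar disc).
#' @param seed Seed for this generator; defaults to a child stream of
#'   `cfg$seed`.
#' @return A `bead_tracks` tibble with columns `track_id`, `frame`, `x`,
#'   `y` (micrometres), ordered by track then frame.
#' @export
#' @examples
#' cfg <- scene_config(seed = 7)
#' f <- generate_field(field_spec("affine", affine_matrix = diag(c(1.05, 1.05))), cfg)
#' tr <- simulate_bead_tracks(50, f, noise_sd = 0, cfg)
#' dplyr::count(tr, frame)
simulate_bead_tracks <- function(n_beads, field, noise_sd, cfg,
                                 region = c("image", "pillar"),
                                 seed = child_seed(cfg$seed, "beads")) {
  stopifnot(n_beads > 0, noise_sd >= 0, field$spec$n_frames >= 2)
  region <- match.arg(region)
  set.seed(seed)
  n_frames <- field$spec$n_frames
  p0 <- if (region == "pillar") {
    runif_disc(n_beads, cfg$pillar_center, cfg$pillar_radius)
  } else {
    extent <- rev(cfg$image_shape) * cfg$pixel_size
    cbind(x = stats::runif(n_beads, 0, extent[1]),
          y = stats::runif(n_beads, 0, extent[2]))
  }
  u_full <- field_displacement(field, p0)
  frames <- rep(seq_len(n_frames) - 1L, each = n_beads)
  s <- field$spec$ramp[frames + 1L]
  x_true <- rep(p0[, 1], n_frames) + s * rep(u_full[, 1], n_frames)
  y_true <- rep(p0[, 2], n_frames) + s * rep(u_full[, 2], n_frames)
  out <- tibble::tibble(
    track_id = rep(seq_len(n_beads), n_frames),
    frame = frames,
    x = x_true + stats::rnorm(length(x_true), 0, noise_sd),
    y = y_true + stats::rnorm(length(y_true), 0, noise_sd))
  out <- dplyr::arrange(out, .data$track_id, .data$frame)
  truth <- dplyr::arrange(
    tibble::tibble(track_id = rep(seq_len(n_beads), n_frames), frame = frames,
                   x = x_true, y = y_true),
    .data$track_id, .data$frame)
  attr(out, "truth") <- truth
  class(out) <- c("bead_tracks", class(out))
  out
}

#' Simulate a pattern-following cell population
#'
#' Cell centroids are uniform on the patterned annulus; each orientation is
#' the local pattern orientation (the polar angle, axial) plus wrapped
#' Gaussian angular noise, reduced to `[0, 180)`.
#'
#' @param pattern A `radial_pattern` from [make_pattern()] (or a
#'   [pattern_spec()] plus `cfg`).
#' @param n_cells Number of cells.
#' @param angular_noise_sd Wrapped-normal angular noise, degrees.
#' @param cfg A [scene_config()]; taken from `pattern` when omitted.
#' @param seed Seed; defaults to a child stream of `cfg$seed`.
#' @param bias_fun Optional function of radius (micrometres) returning an
#'   additive orientation bias in degrees, used to inject band-specific
#'   misalignment in validation fixtures.
#' @return A `cell_records` tibble: `cell_id`, `kind`, `x`, `y`,
#'   `orientation` (degrees axial), `true_orientation` (noise-free).
#' @export
simulate_cell_population <- function(pattern, n_cells, angular_noise_sd,
                                     cfg = NULL, seed = NULL,
                                     bias_fun = NULL) {
  if (inherits(pattern, "radial_pattern")) {
    spec <- pattern$spec
    cfg <- cfg %||% pattern$cfg
  } else spec <- pattern
  stopifnot(inherits(spec, "pattern_spec"), inherits(cfg, "scene_config"),
            n_cells > 0, angular_noise_sd >= 0)
  seed <- seed %||% child_seed(cfg$seed, "cells")
  set.seed(seed)
  p <- runif_disc(n_cells, spec$center, spec$r_outer, spec$r_inner)
  ev <- pattern_eval(spec, p[, 1], p[, 2])
  bias <- if (is.null(bias_fun)) 0 else bias_fun(ev$r)
  orient <- wrap_axial(ev$orientation + bias +
                         stats::rnorm(n_cells, 0, angular_noise_sd))
  out <- tibble::tibble(cell_id = seq_len(n_cells), kind = "nucleus",
                        x = p[, 1], y = p[, 2], orientation = orient,
                        true_orientation = wrap_axial(ev$orientation + bias))
  class(out) <- c("cell_records", class(out))
  out
}

#' Simulate migration trajectories as a persistent random walk
#'
#' Each cell starts at a uniform random point inside the pillar with a
#' uniform random heading, then takes steps whose speed is lognormal and
#' whose turning angle is von Mises about the previous heading with
#' concentration `kappa`. Depending on the condition the heading is also
#' relaxed toward a common drift direction (collective motion of the
#' undeformed conditions) or the local outward radial direction (deformed
#' conditions). Trajectories reflect at the image boundary so that no
#' track is truncated.
#'
#' @param spec A [migration_spec()].
#' @param n_cells Number of trajectories.
#' @param n_frames Number of frames (positions per track); the emulated
#'   migration protocol is one frame per minute over one hour.
#' @param cfg A [scene_config()].
#' @param seed Seed; defaults to a child stream of `cfg$seed`.
#' @return A `trajectory_set` tibble: `track_id`, `frame`, `x`, `y`, with
#'   attributes `condition` and `frame_interval`.
#' @export
#' @examples
#' cfg <- scene_config(seed = 3)
#' tr <- simulate_migration(migration_spec("patterned_deformed"), 10, 61, cfg)
#' attr(tr, "condition")
simulate_migration <- function(spec, n_cells, n_frames = 61L, cfg,
                               seed = child_seed(cfg$seed, spec$condition)) {
  stopifnot(inherits(spec, "migration_spec"), n_cells > 0, n_frames >= 2)
  set.seed(seed)
  extent <- rev(cfg$image_shape) * cfg$pixel_size
  p <- runif_disc(n_cells, cfg$pillar_center, cfg$pillar_radius)
  heading <- stats::runif(n_cells, -180, 180)
  xs <- matrix(NA_real_, n_cells, n_frames)
  ys <- matrix(NA_real_, n_cells, n_frames)
  xs[, 1] <- p[, 1]; ys[, 1] <- p[, 2]
  kappa <- spec$turning_concentration
  for (f in 2:n_frames) {
    turn <- rvonmises_deg(n_cells, 0, kappa)
    heading <- wrap_directional(heading + turn)
    if (!is.null(spec$drift) && spec$drift_weight > 0) {
      heading <- wrap_directional(
        heading + spec$drift_weight * wrap_directional(spec$drift - heading))
    }
    if (spec$radial_bias > 0) {
      radial <- rad2deg(atan2(-(ys[, f - 1L] - cfg$pillar_center[2]),
                              xs[, f - 1L] - cfg$pillar_center[1]))
      heading <- wrap_directional(
        heading + spec$radial_bias * wrap_directional(radial - heading))
    }
    speed <- stats::rlnorm(n_cells, spec$speed_lognormal[["meanlog"]],
                           spec$speed_lognormal[["sdlog"]])
    step <- speed * cfg$frame_interval
    # heading is mathematical (y-up); storage y runs downward
    nx <- xs[, f - 1L] + step * cos(deg2rad(heading))
    ny <- ys[, f - 1L] - step * sin(deg2rad(heading))
    refl_x <- nx < 0 | nx > extent[1]
    refl_y <- ny < 0 | ny > extent[2]
    nx <- abs(nx); nx <- ifelse(nx > extent[1], 2 * extent[1] - nx, nx)
    ny <- abs(ny); ny <- ifelse(ny > extent[2], 2 * extent[2] - ny, ny)
    heading[refl_x] <- wrap_directional(180 - heading[refl_x])
    heading[refl_y] <- -heading[refl_y]
    xs[, f] <- nx; ys[, f] <- ny
  }
  out <- tibble::tibble(
    track_id = rep(seq_len(n_cells), each = n_frames),
    frame = rep(seq_len(n_frames) - 1L, n_cells),
    x = as.vector(t(xs)), y = as.vector(t(ys)))
  attr(out, "condition") <- spec$condition
  attr(out, "frame_interval") <- cfg$frame_interval
  class(out) <- c("trajectory_set", class(out))
  out
}

#' Render bead positions as a fluorescence image stack
#'
#' Each bead becomes an isotropic Gaussian spot of standard deviation
#' `spot_sigma_px`; a Poisson photon noise model plus Gaussian read noise is
#' applied on top of a constant background.
#'
#' @param tracks A tibble with `track_id`, `frame`, `x`, `y` (micrometres).
#' @param cfg A [scene_config()].
#' @param spot_sigma_px Spot standard deviation in pixels; values below
#'   0.5 px are sub-Nyquist and trigger a warning.
#' @param peak Expected photon count at the spot centre.
#' @param background Expected background photon count per pixel.
#' @param read_noise Gaussian read-noise standard deviation (counts); set
#'   `read_noise = 0` and `peak` large for an effectively noise-free stack.
#' @param poisson Logical; apply Poisson photon noise (default `TRUE`).
#' @param frames Frame indices to render; defaults to the frames present
#'   in `tracks`. Passing frames explicitly renders background-only images
#'   for frames without spots.
#' @param seed Seed for the noise; defaults to a child stream of
#'   `cfg$seed`.
#' @return A list of numeric matrices (one per frame, values in photon
#'   counts), with attribute `truth` echoing the input positions.
#' @export
render_bead_stack <- function(tracks, cfg, spot_sigma_px = 1.5, peak = 500,
                              background = 10, read_noise = 2,
                              poisson = TRUE, frames = NULL,
                              seed = child_seed(cfg$seed, "render")) {
  if (spot_sigma_px < 0.5) {
    warning("spot sigma below 0.5 px is under-sampled (sub-Nyquist)")
  }
  set.seed(seed)
  rows <- cfg$image_shape[1]; cols <- cfg$image_shape[2]
  frames <- frames %||% sort(unique(tracks$frame))
  if (length(frames) == 0L) {
    warning("no frames to render: empty track table and no frames given")
    out <- list()
    attr(out, "truth") <- tracks
    return(out)
  }
  win <- ceiling(4 * spot_sigma_px)
  out <- lapply(frames, function(f) {
    img <- matrix(background, rows, cols)
    sub <- tracks[tracks$frame == f, ]
    for (i in seq_len(nrow(sub))) {
      cx <- sub$x[i] / cfg$pixel_size + 0.5  # pixel-centre convention
      cy <- sub$y[i] / cfg$pixel_size + 0.5
      c0 <- max(1L, floor(cx - win)); c1 <- min(cols, ceiling(cx + win))
      r0 <- max(1L, floor(cy - win)); r1 <- min(rows, ceiling(cy + win))
      if (c0 > c1 || r0 > r1) next
      px <- seq(c0, c1); py <- seq(r0, r1)
      gx <- exp(-((px - cx)^2) / (2 * spot_sigma_px^2))
      gy <- exp(-((py - cy)^2) / (2 * spot_sigma_px^2))
      img[py, px] <- img[py, px] + peak * outer(gy, gx)
    }
    if (poisson) img <- matrix(stats::rpois(length(img), img), rows, cols)
    if (read_noise > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, read_noise), rows, cols)
    }
    img
  })
  names(out) <- paste0("frame_", frames)
  attr(out, "truth") <- tracks
  out
}

#' Render a cell population as a nuclei label image
#'
#' Each cell is drawn as a filled ellipse with the given semi-axes at its
#' recorded orientation; pixel values are the cell ids (0 background).
#' Overlapping cells keep the higher id (later cells draw on top).
#'
#' @param cells A `cell_records` tibble (columns `cell_id`, `x`, `y`,
#'   `orientation`).
#' @param cfg A [scene_config()].
#' @param semi_major,semi_minor Ellipse semi-axes in micrometres.
#' @return An integer label matrix.
#' @export
render_nuclei_labels <- function(cells, cfg, semi_major = 10,
                                 semi_minor = 4) {
  rows <- cfg$image_shape[1]; cols <- cfg$image_shape[2]
  img <- matrix(0L, rows, cols)
  px <- cfg$pixel_size
  for (i in seq_len(nrow(cells))) {
    phi <- deg2rad(cells$orientation[i])
    # math angle -> storage: direction (cos phi, -sin phi) in (x, y_down)
    cx <- cells$x[i]; cy <- cells$y[i]
    ext <- max(semi_major, semi_minor)
    c0 <- max(1L, floor((cx - ext) / px)); c1 <- min(cols, ceiling((cx + ext) / px))
    r0 <- max(1L, floor((cy - ext) / px)); r1 <- min(rows, ceiling((cy + ext) / px))
    if (c0 > c1 || r0 > r1) next
    xs <- (seq(c0, c1) - 0.5) * px - cx
    ys <- (seq(r0, r1) - 0.5) * px - cy
    X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    Y <- matrix(ys, length(ys), length(xs))
    u <- X * cos(phi) - Y * sin(phi)   # along major axis
    v <- -X * sin(phi) - Y * cos(phi)  # along minor axis (y-flip applied)
    hit <- (u / semi_major)^2 + (v / semi_minor)^2 <= 1
    blk <- img[seq(r0, r1), seq(c0, c1), drop = FALSE]
    blk[hit] <- as.integer(cells$cell_id[i])
    img[seq(r0, r1), seq(c0, c1)] <- blk
  }
  img
}

#' Write a synthetic scene to disk
#'
#' Writes the standard artefact set of a synthetic experiment: multi-frame
#' TIFF stacks per rendered channel, `tracks.csv` (`track_id`, `frame`,
#' `x_um`, `y_um`), `cells.csv` (`cell_id`, `x_um`, `y_um`,
#' `orientation_deg`) and `scene.yaml` echoing the full configuration.
#'
#' @param dir Output directory (created if missing).
#' @param cfg A [scene_config()].
#' @param tracks Optional tibble of tracks.
#' @param cells Optional `cell_records` tibble.
#' @param stacks Optional named list of image stacks (each a list of
#'   matrices) written as `<name>.tif`.
#' @param extra Optional named list merged into `scene.yaml`.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(dir, cfg, tracks = NULL, cells = NULL,
                        stacks = NULL, extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(tracks)) {
    utils::write.csv(
      data.frame(track_id = tracks$track_id, frame = tracks$frame,
                 x_um = tracks$x, y_um = tracks$y),
      file.path(dir, "tracks.csv"), row.names = FALSE)
  }
  if (!is.null(cells)) {
    utils::write.csv(
      data.frame(cell_id = cells$cell_id, x_um = cells$x, y_um = cells$y,
                 orientation_deg = cells$orientation),
      file.path(dir, "cells.csv"), row.names = FALSE)
  }
  if (!is.null(stacks)) {
    for (nm in names(stacks)) {
      st <- stacks[[nm]]
      mx <- max(1, vapply(st, max, numeric(1)))
      tiff::writeTIFF(lapply(st, function(m) pmin(pmax(m / mx, 0), 1)),
                      file.path(dir, paste0(nm, ".tif")), bits.per.sample = 16L)
    }
  }
  yaml::write_yaml(c(list(scene = unclass(cfg)), extra),
                   file.path(dir, "scene.yaml"))
  invisible(dir)
}
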