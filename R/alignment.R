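# Quantification of contact-guidance alignment on a radial micropattern:
# theta-sector partition of the pillar, the angular-alignment statistic
# gamma (axial difference between object orientation and sector
# orientation), Gaussian and linear fits, and stratification by radial
# band.

#' Polar sector partition of the pillar area
#'
#' Divides the pillar into angular sectors of `theta_width` degrees and
#' annular bands with edges `r_edges`. A sector's orientation is the axial
#' angle of its bisecting radius, reduced to `[0, 180)`. Points exactly on
#' a sector boundary belong to the sector whose lower edge it is, i.e. the
#' higher-index of the two adjacent sectors.
#'
#' @param center Numeric `c(x, y)` centre in micrometres.
#' @param theta_width Sector width in degrees; must divide 360 (default 10,
#'   giving 36 sectors).
#' @param r_edges Strictly increasing radii (micrometres) bounding the
#'   annular bands; the analysis annulus is `[min(r_edges), max(r_edges)]`.
#' @return An object of class `sector_partition`.
#' @export
#' @examples
#' p <- sector_partition(c(0, 0), 10, r_edges = c(0, 50, 100, 150))
#' p$n_sectors
sector_partition <- function(center, theta_width = 10,
                             r_edges = NULL) {
  stopifnot(length(center) == 2L, theta_width > 0)
  if (abs(360 %% theta_width) > 1e-9) {
    stop("theta_width must divide 360 evenly", call. = FALSE)
  }
  if (is.null(r_edges)) r_edges <- c(0, 50, 100, 150)
  stopifnot(length(r_edges) >= 2L, all(diff(r_edges) > 0))
  structure(
    list(center = as.numeric(center), theta_width = theta_width,
         n_sectors = as.integer(round(360 / theta_width)),
         r_edges = as.numeric(r_edges)),
    class = "sector_partition")
}

#' Locate points in a sector partition
#'
#' @param partition A [sector_partition()].
#' @param x,y Point coordinates in micrometres (storage convention,
#'   y down; the y-flip to mathematical polar angles is applied here).
#' @return A tibble with `r`, `theta` (polar angle, degrees in
#'   `[0, 360)`), `sector` (0-based index), `sector_orientation` (degrees,
#'   axial), `band` (1-based annular band index, `NA` outside), `inside`
#'   (within the analysis annulus).
#' @export
locate_in_partition <- function(partition, x, y) {
  dx <- x - partition$center[1]
  dy <- -(y - partition$center[2])
  r <- sqrt(dx^2 + dy^2)
  theta <- rad2deg(atan2(dy, dx)) %% 360
  sector <- floor(theta / partition$theta_width) %% partition$n_sectors
  sector_orientation <- wrap_axial((sector + 0.5) * partition$theta_width)
  edges <- partition$r_edges
  band <- findInterval(r, edges, rightmost.closed = TRUE)
  inside <- band >= 1 & band <= length(edges) - 1L
  band[!inside] <- NA_integer_
  tibble::tibble(r = r, theta = theta, sector = as.integer(sector),
                 sector_orientation = sector_orientation,
                 band = as.integer(band), inside = inside)
}

#' Angular alignment of objects to the radial pattern
#'
#' For each record, gamma is the axial difference between the object's
#' orientation and a reference pattern orientation at its centroid, wrapped
#' to `[-90, 90)`. With `reference = "sector"` (the default, matching
#' sector-based workflows) the reference is the orientation of the
#' theta-sector containing the centroid, so even perfectly radial objects
#' spread gamma uniformly over half the sector width; with
#' `reference = "local"` it is the exact polar angle of the centroid, so
#' gamma isolates the angular noise alone. Records outside the analysis
#' annulus are excluded (and counted in the `n_excluded` attribute).
#'
#' @param records Tibble with columns `x`, `y`, `orientation` (degrees
#'   axial); typically [simulate_cell_population()] output or measured
#'   nuclei.
#' @param partition A [sector_partition()].
#' @param reference `"sector"` (bisecting-radius orientation of the
#'   containing sector) or `"local"` (exact polar angle of the centroid).
#' @return A `gamma_table` tibble: the included records plus `r`, `sector`,
#'   `sector_orientation`, `band` and `gamma` (degrees in `[-90, 90)`).
#' @export
#' @examples
#' p <- sector_partition(c(0, 0), 10, c(10, 150))
#' rec <- tibble::tibble(x = 100, y = 0, orientation = 45)
#' angular_alignment(rec, p)$gamma  # 45 - 0 = 45
angular_alignment <- function(records, partition,
                              reference = c("sector", "local")) {
  stopifnot(all(c("x", "y", "orientation") %in% names(records)))
  reference <- match.arg(reference)
  loc <- locate_in_partition(partition, records$x, records$y)
  out <- dplyr::bind_cols(tibble::as_tibble(records),
                          loc[, c("r", "theta", "sector",
                                  "sector_orientation", "band")])
  n_total <- nrow(out)
  out <- out[loc$inside, ]
  ref <- if (reference == "sector") out$sector_orientation
         else wrap_axial(out$theta)
  out$gamma <- wrap_axial_diff(out$orientation - ref)
  attr(out, "n_excluded") <- n_total - nrow(out)
  attr(out, "reference") <- reference
  class(out) <- c("gamma_table", class(out))
  out
}

#' Gaussian fit of the angular-alignment distribution
#'
#' Two estimates are returned: the maximum-likelihood normal fit on the raw
#' gamma values (primary), and a least-squares Gaussian fit on the binned
#' histogram (reported for parity with histogram-based workflows). A
#' wrapped dispersion estimate from the axial resultant length is included
#' as a cross-check; for sigma below about 20 degrees the wrapping
#' correction is negligible.
#'
#' @param gamma Numeric vector of angular alignments in degrees (or a
#'   `gamma_table`, whose `gamma` column is used).
#' @param binwidth Histogram bin width in degrees for the least-squares
#'   fit (default 5).
#' @return A list of class `gamma_fit`: `mu`, `sigma` (MLE), `mu_hist`,
#'   `sigma_hist` (histogram least squares), `sigma_wrapped`, `n`,
#'   `degenerate`, `histogram` (tibble of bin centres and counts).
#' @export
fit_gamma <- function(gamma, binwidth = 5) {
  if (inherits(gamma, "gamma_table") || is.data.frame(gamma)) {
    gamma <- gamma$gamma
  }
  gamma <- gamma[is.finite(gamma)]
  n <- length(gamma)
  if (n < 10L) stop("fewer than 10 gamma values: fit refused", call. = FALSE)
  mu <- mean(gamma)
  sigma <- sqrt(mean((gamma - mu)^2))
  degenerate <- sigma < 1e-8
  breaks <- seq(-90, 90, by = binwidth)
  h <- graphics::hist(gamma, breaks = breaks, plot = FALSE)
  hist_tb <- tibble::tibble(mid = h$mids, count = h$counts)
  mu_h <- mu; sigma_h <- sigma
  if (!degenerate) {
    fit <- tryCatch(
      stats::nls(count ~ A * exp(-(mid - m)^2 / (2 * s^2)), data = hist_tb,
                 start = list(A = max(h$counts), m = mu, s = max(sigma, 1)),
                 control = stats::nls.control(warnOnly = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      mu_h <- unname(cf["m"]); sigma_h <- abs(unname(cf["s"]))
    }
  }
  structure(
    list(mu = mu, sigma = sigma, mu_hist = mu_h, sigma_hist = sigma_h,
         sigma_wrapped = axial_sd(gamma), n = n, degenerate = degenerate,
         histogram = hist_tb),
    class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf(
    "<gamma_fit> n = %d | MLE mu = %.2f deg, sigma = %.2f deg%s\n",
    x$n, x$mu, x$sigma, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

# Per-sector axial mean orientations, unwrapped to the branch nearest each
# sector's orientation so a linear fit against sector orientation is
# meaningful despite the mod-180 ambiguity.
sector_means <- function(gamma_table, n_min = 5) {
  gamma_table |>
    dplyr::group_by(.data$sector, .data$sector_orientation) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_orientation = axial_mean(.data$orientation),
      resultant = axial_resultant_length(.data$orientation),
      .groups = "drop") |>
    dplyr::filter(.data$n >= n_min, !is.na(.data$mean_orientation),
                  .data$resultant > 1e-6) |>
    dplyr::mutate(mean_unwrapped = .data$sector_orientation +
                    wrap_axial_diff(.data$mean_orientation -
                                      .data$sector_orientation))
}

#' Regression of object orientation on sector orientation
#'
#' Ordinary least squares of the per-sector axial mean object orientation
#' (unwrapped to each sector's branch) against the sector orientation. A
#' population following the pattern gives slope near 1 and intercept near
#' 0; a population with a fixed lab-frame orientation gives slope near 0.
#'
#' @param gamma_table A `gamma_table` from [angular_alignment()].
#' @param n_min Minimum objects per sector for inclusion (default 5).
#' @return A list of class `alignment_regression`: `slope`, `intercept`,
#'   `r_squared`, `n_sectors`, `per_sector` (tibble), `fit` (the `lm`).
#' @export
orientation_regression <- function(gamma_table, n_min = 5) {
  ms <- sector_means(gamma_table, n_min)
  if (nrow(ms) < 5L) {
    stop("fewer than 5 sectors with at least n_min objects", call. = FALSE)
  }
  fit <- stats::lm(mean_unwrapped ~ sector_orientation, data = ms)
  # a constant-orientation population yields an exact fit; the summary
  # warning about it is expected, not actionable
  sm <- suppressWarnings(summary(fit))
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared, n_sectors = nrow(ms),
         per_sector = ms, fit = fit),
    class = "alignment_regression")
}

#' @export
print.alignment_regression <- function(x, ...) {
  cat(sprintf(
    "<alignment_regression> slope = %.3f, intercept = %.2f deg, r^2 = %.3f (%d sectors)\n",
    x$slope, x$intercept, x$r_squared, x$n_sectors))
  invisible(x)
}

#' Alignment statistics stratified by radial band
#'
#' Repeats the gamma pipeline (Gaussian fit and, where enough sectors
#' qualify, the orientation regression) within each annular band of the
#' partition, so that a radial gradient of deformation can be checked for
#' an effect on alignment.
#'
#' @param records Tibble with `x`, `y`, `orientation`.
#' @param partition A [sector_partition()] whose `r_edges` define the
#'   bands.
#' @param n_min Minimum objects per sector for the regression; bands with
#'   fewer than 10 objects overall are reported as insufficient.
#' @param reference Passed to [angular_alignment()].
#' @return A tibble with one row per band: `band`, `r_lo`, `r_hi`, `n`,
#'   `status` (`"ok"` or `"insufficient"`), `mu`, `sigma`, `slope`,
#'   `r_squared` (`NA` where not computable).
#' @export
alignment_by_rband <- function(records, partition, n_min = 5,
                               reference = c("sector", "local")) {
  gt <- angular_alignment(records, partition, reference)
  edges <- partition$r_edges
  n_bands <- length(edges) - 1L
  purrr::map_dfr(seq_len(n_bands), function(b) {
    sub <- gt[!is.na(gt$band) & gt$band == b, ]
    base <- tibble::tibble(band = b, r_lo = edges[b], r_hi = edges[b + 1L],
                           n = nrow(sub))
    if (nrow(sub) < 10L) {
      return(dplyr::mutate(base, status = "insufficient", mu = NA_real_,
                           sigma = NA_real_, slope = NA_real_,
                           r_squared = NA_real_))
    }
    f <- fit_gamma(sub)
    reg <- tryCatch(orientation_regression(sub, n_min), error = function(e) NULL)
    dplyr::mutate(base, status = "ok", mu = f$mu, sigma = f$sigma,
                  slope = if (is.null(reg)) NA_real_ else reg$slope,
                  r_squared = if (is.null(reg)) NA_real_ else reg$r_squared)
  })
}

#' Measure nucleus orientations from a label image
#'
#' Computes each labelled object's intensity-free second-moment ellipse:
#' centroid, area, major/minor axis lengths and the axial orientation of
#' the major axis (mathematical convention, y up). Objects touching the
#' image border are excluded; near-circular objects (axis ratio below
#' `min_axis_ratio`) are flagged unreliable and excluded from gamma
#' analyses.
#'
#' @param labels Integer matrix of object labels (0 = background), e.g.
#'   from [render_nuclei_labels()] or `EBImage::bwlabel`.
#' @param pixel_size Micrometres per pixel.
#' @param min_axis_ratio Minimum major/minor ratio for a reliable
#'   orientation (default 1.05).
#' @return A `cell_records` tibble: `object_id`, `x`, `y` (micrometres),
#'   `area` (square micrometres), `major`, `minor` (full axis lengths,
#'   micrometres), `aspect_ratio`, `orientation` (degrees in `[0, 180)`),
#'   `reliable`.
#' @export
measure_nucleus_orientation <- function(labels, pixel_size = 1,
                                        min_axis_ratio = 1.05) {
  stopifnot(is.matrix(labels))
  ids <- sort(setdiff(unique(as.vector(labels)), 0))
  rows <- nrow(labels); cols <- ncol(labels)
  out <- purrr::map_dfr(ids, function(id) {
    idx <- which(labels == id, arr.ind = TRUE)
    touches <- any(idx[, 1] %in% c(1L, rows)) || any(idx[, 2] %in% c(1L, cols))
    xs <- (idx[, 2] - 0.5) * pixel_size
    ys <- (idx[, 1] - 0.5) * pixel_size
    mx <- mean(xs); my <- mean(ys)
    # + pixel_size^2/12: variance of the uniform square pixel footprint
    sxx <- mean((xs - mx)^2) + pixel_size^2 / 12
    syy <- mean((ys - my)^2) + pixel_size^2 / 12
    sxy <- mean((xs - mx) * (ys - my))
    tr <- sxx + syy
    dd <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
    l1 <- tr / 2 + dd; l2 <- max(tr / 2 - dd, 0)
    # y-flip: math-frame covariance has Cxy = -sxy
    orient <- wrap_axial(rad2deg(0.5 * atan2(-2 * sxy, sxx - syy)))
    major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
    ar <- if (minor > 0) major / minor else Inf
    tibble::tibble(object_id = id, x = mx, y = my,
                   area = length(xs) * pixel_size^2,
                   major = major, minor = minor, aspect_ratio = ar,
                   orientation = orient,
                   reliable = !touches & is.finite(ar) & ar >= min_axis_ratio,
                   border = touches)
  })
  out <- out[!out$border, setdiff(names(out), "border")]
  class(out) <- c("cell_records", class(out))
  out
}

gaussian_kernel <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  ax <- seq(-half, half)
  k <- outer(exp(-ax^2 / (2 * sigma^2)), exp(-ax^2 / (2 * sigma^2)))
  k / sum(k)
}

#' Dominant orientation of an image tile
#'
#' Structure-tensor orientation analysis: image gradients are computed with
#' two-dimensional Gaussian-derivative filters (whose frequency response is
#' isotropic, so grating orientations are estimated without angular bias),
#' the tensor components are Gaussian-smoothed, and an
#' energy-and-coherence-weighted axial histogram of the local stripe
#' orientation (perpendicular to the gradient) is accumulated. The dominant
#' orientation is the smoothed histogram mode, refined by the weighted
#' axial mean of the orientations within two bins of the peak; the axial
#' dispersion and mean coherence are returned alongside. Tiles whose mean
#' coherence falls below `coherence_min` are flagged isotropic, with an
#' `NA` orientation.
#'
#' @param tile Numeric matrix.
#' @param gradient_sigma Scale of the Gaussian-derivative gradient filters
#'   in pixels (default 1).
#' @param smoothing_sigma Tensor smoothing scale in pixels (default 2).
#' @param binwidth Histogram bin width in degrees (default 2).
#' @param coherence_min Isotropy threshold on energy-weighted mean
#'   coherence (default 0.35; oriented textures score well above it,
#'   white noise well below).
#' @return A list of class `dominant_orientation`: `orientation` (degrees
#'   axial, `NA` if isotropic), `dispersion` (degrees), `coherence`,
#'   `isotropic`, `histogram` (tibble).
#' @export
measure_dominant_orientation <- function(tile, gradient_sigma = 1,
                                         smoothing_sigma = 2,
                                         binwidth = 2,
                                         coherence_min = 0.35) {
  stopifnot(is.matrix(tile), nrow(tile) >= 5, ncol(tile) >= 5)
  half <- max(1L, ceiling(3 * gradient_sigma))
  ax <- seq(-half, half)
  g1 <- exp(-ax^2 / (2 * gradient_sigma^2))
  dg <- -ax / gradient_sigma^2 * g1
  kx <- outer(g1, dg); kx <- kx / sum(abs(kx))   # d/dx (columns)
  ky <- outer(dg, g1); ky <- ky / sum(abs(ky))   # d/dy (rows)
  gx <- EBImage::filter2(tile, kx, boundary = "replicate")
  gy <- EBImage::filter2(tile, ky, boundary = "replicate")
  k <- gaussian_kernel(smoothing_sigma)
  Jxx <- EBImage::filter2(gx * gx, k)
  Jyy <- EBImage::filter2(gy * gy, k)
  Jxy <- EBImage::filter2(gx * gy, k)
  energy <- Jxx + Jyy
  coher <- ifelse(energy > 1e-12,
                  sqrt((Jxx - Jyy)^2 + 4 * Jxy^2) / energy, 0)
  # gradient orientation in the math frame (y-flip), stripes run
  # perpendicular to the gradient
  grad_or <- 0.5 * atan2(-2 * Jxy, Jxx - Jyy)
  stripe <- wrap_axial(rad2deg(grad_or) + 90)
  w <- as.vector(energy * coher)
  mean_coh <- sum(as.vector(coher) * as.vector(energy)) /
    max(sum(energy), 1e-12)
  breaks <- seq(0, 180, by = binwidth)
  bin <- pmin(findInterval(as.vector(stripe), breaks,
                           rightmost.closed = TRUE), length(breaks) - 1L)
  counts <- vapply(seq_len(length(breaks) - 1L),
                   function(b) sum(w[bin == b]), numeric(1))
  # circular smoothing over 5 bins
  sk <- c(1, 2, 3, 2, 1); sk <- sk / sum(sk)
  nb <- length(counts)
  sm <- vapply(seq_len(nb), function(i) {
    sum(sk * counts[((i - 3 + seq_len(5) - 1) %% nb) + 1])
  }, numeric(1))
  hist_tb <- tibble::tibble(mid = breaks[-length(breaks)] + binwidth / 2,
                            weight = counts, smoothed = sm)
  isotropic <- mean_coh < coherence_min
  if (isotropic) {
    orient <- NA_real_; disp <- NA_real_
  } else {
    # refine the mode by the weighted axial mean of orientations within
    # two bins of the peak (beats the half-bin quantisation of the mode)
    i0 <- which.max(sm)
    near <- abs(wrap_axial_diff(as.vector(stripe) - hist_tb$mid[i0])) <=
      2 * binwidth
    wn <- w[near]
    if (sum(wn) > 0) {
      a2 <- deg2rad(2 * as.vector(stripe)[near])
      orient <- wrap_axial(rad2deg(atan2(sum(wn * sin(a2)),
                                         sum(wn * cos(a2)))) / 2)
    } else orient <- hist_tb$mid[i0]
    # weighted axial dispersion around the circle
    ang2 <- deg2rad(2 * hist_tb$mid)
    cbar <- sum(sm * cos(ang2)) / sum(sm)
    sbar <- sum(sm * sin(ang2)) / sum(sm)
    r2 <- sqrt(cbar^2 + sbar^2)
    disp <- if (r2 > 0) rad2deg(sqrt(-2 * log(r2))) / 2 else NA_real_
  }
  structure(
    list(orientation = orient, dispersion = disp, coherence = mean_coh,
         isotropic = isotropic, histogram = hist_tb),
    class = "dominant_orientation")
}
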