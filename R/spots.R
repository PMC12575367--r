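# LoG spot detection and two-step track linking (greedy nearest-neighbour
# frame-to-frame linking followed by gap closing), used for both fiducial
# beads and migrating nuclei.

log_kernel <- function(sigma) {
  half <- ceiling(3 * sigma)
  ax <- seq(-half, half)
  X <- matrix(ax, 2 * half + 1, 2 * half + 1, byrow = TRUE)
  Y <- t(X)
  r2 <- X^2 + Y^2
  # negative scale-normalised LoG: positive response at bright blobs
  k <- -sigma^2 * (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k - mean(k)  # zero-sum so flat background gives zero response
}

#' Detect bright spots with a Laplacian-of-Gaussian filter
#'
#' Filters the image with a scale-normalised LoG kernel matched to
#' `sigma_px`, finds local maxima of the response above a quality
#' threshold, and refines each to sub-pixel accuracy with an
#' intensity-weighted centroid in a window of half-width `2 * sigma_px`
#' around the maximum (background-subtracted with the window minimum).
#'
#' @param image Numeric matrix (a single frame).
#' @param sigma_px Expected spot standard deviation in pixels.
#' @param quality_threshold Minimum LoG response for a detection. When
#'   `NULL` (default) a robust data-driven threshold is used: the larger
#'   of `median(resp) + 8 * mad(resp)` and 2% of the peak response (the
#'   floor suppresses numerically flat ripples on clean backgrounds).
#' @param pixel_size Micrometres per pixel used to scale the output
#'   coordinates.
#' @return A tibble with columns `x`, `y` (micrometres), `quality` (LoG
#'   response at the maximum). Blank or saturated frames return zero rows
#'   with a warning.
#' @export
detect_spots <- function(image, sigma_px, quality_threshold = NULL,
                         pixel_size = 1) {
  stopifnot(is.matrix(image), sigma_px > 0)
  rng <- range(image, finite = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) < .Machine$double.eps) {
    warning("blank or saturated frame: no spots detected")
    return(tibble::tibble(x = numeric(0), y = numeric(0),
                          quality = numeric(0)))
  }
  resp <- EBImage::filter2(image, log_kernel(sigma_px),
                           boundary = "replicate")
  thr <- quality_threshold %||%
    max(stats::median(resp) + 8 * stats::mad(resp), 0.02 * max(resp))
  rows <- nrow(resp); cols <- ncol(resp)
  inner_r <- 2:(rows - 1); inner_c <- 2:(cols - 1)
  ctr <- resp[inner_r, inner_c]
  is_max <- ctr > thr &
    ctr >= resp[inner_r - 1, inner_c] & ctr >= resp[inner_r + 1, inner_c] &
    ctr >= resp[inner_r, inner_c - 1] & ctr >= resp[inner_r, inner_c + 1] &
    ctr >= resp[inner_r - 1, inner_c - 1] & ctr >= resp[inner_r - 1, inner_c + 1] &
    ctr >= resp[inner_r + 1, inner_c - 1] & ctr >= resp[inner_r + 1, inner_c + 1]
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(tibble::tibble(x = numeric(0), y = numeric(0),
                          quality = numeric(0)))
  }
  pr <- idx[, 1] + 1L  # back to full-image indices
  pc <- idx[, 2] + 1L
  # non-maximum suppression: response plateaus (a spot centred between
  # pixels) yield several equal maxima; keep one per sigma-sized cluster
  qv <- resp[cbind(pr, pc)]
  ord <- order(-qv, pr, pc)
  keep <- logical(length(ord))
  min_sep2 <- max(1, sigma_px)^2
  for (i in ord) {
    if (!any(keep & ((pr - pr[i])^2 + (pc - pc[i])^2) <= min_sep2)) {
      keep[i] <- TRUE
    }
  }
  pr <- pr[keep]; pc <- pc[keep]
  win <- max(1L, ceiling(2 * sigma_px))
  n <- length(pr)
  cx <- numeric(n); cy <- numeric(n); q <- numeric(n)
  for (i in seq_len(n)) {
    r0 <- max(1L, pr[i] - win); r1 <- min(rows, pr[i] + win)
    c0 <- max(1L, pc[i] - win); c1 <- min(cols, pc[i] + win)
    blk <- image[r0:r1, c0:c1, drop = FALSE]
    blk <- blk - min(blk)
    tot <- sum(blk)
    if (tot <= 0) { cx[i] <- pc[i]; cy[i] <- pr[i] }
    else {
      cy[i] <- sum(blk * matrix(r0:r1, nrow(blk), ncol(blk))) / tot
      cx[i] <- sum(blk * matrix(c0:c1, nrow(blk), ncol(blk), byrow = TRUE)) / tot
    }
    q[i] <- resp[pr[i], pc[i]]
  }
  tibble::tibble(x = (cx - 0.5) * pixel_size, y = (cy - 0.5) * pixel_size,
                 quality = q)
}

#' Detect spots in every frame of a stack
#'
#' @param stack List of matrices (frames, 0-based frame index taken from
#'   list order or names `frame_<f>`).
#' @inheritParams detect_spots
#' @return A tibble with columns `frame`, `x`, `y`, `quality`.
#' @export
detect_spots_stack <- function(stack, sigma_px, quality_threshold = NULL,
                               pixel_size = 1) {
  frames <- if (!is.null(names(stack)) &&
                all(grepl("^frame_", names(stack)))) {
    as.integer(sub("^frame_", "", names(stack)))
  } else seq_along(stack) - 1L
  purrr::map2_dfr(stack, frames, function(img, f) {
    d <- suppressWarnings(
      detect_spots(img, sigma_px, quality_threshold, pixel_size))
    if (nrow(d)) d$frame <- f else d$frame <- integer(0)
    d
  }) |> dplyr::relocate("frame")
}

# Greedy globally cost-ordered assignment between two point sets within
# max_dist. Ties in cost are broken by lowest (from, to) index. Returns a
# two-column matrix of (from, to) index pairs.
greedy_match <- function(p_from, p_to, max_dist) {
  if (nrow(p_from) == 0L || nrow(p_to) == 0L) {
    return(matrix(integer(0), 0, 2))
  }
  d <- outer(p_from[, 1], p_to[, 1], "-")^2 +
    outer(p_from[, 2], p_to[, 2], "-")^2
  cand <- which(d <= max_dist^2, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(matrix(integer(0), 0, 2))
  ord <- order(d[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  used_from <- logical(nrow(p_from)); used_to <- logical(nrow(p_to))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    a <- cand[i, 1]; b <- cand[i, 2]
    if (!used_from[a] && !used_to[b]) {
      keep[i] <- TRUE; used_from[a] <- TRUE; used_to[b] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

#' Link per-frame detections into tracks
#'
#' Two-step linking: (1) greedy, globally cost-ordered nearest-neighbour
#' assignment between consecutive frames under a maximum displacement;
#' (2) gap closing, joining the end of one track segment to the start of
#' another when the frame gap is at most `max_gap` and the distance is at
#' most `max_disp` per skipped frame interval. Cost ties are resolved
#' deterministically by lowest detection index.
#'
#' @param detections Tibble with columns `frame`, `x`, `y` (micrometres).
#' @param max_disp Maximum displacement per frame interval (micrometres).
#' @param max_gap Maximum number of missing frames bridged by gap closing
#'   (0 disables gap closing).
#' @return A `bead_tracks` tibble (`track_id`, `frame`, `x`, `y`), track
#'   ids numbered by order of first appearance.
#' @export
link_tracks <- function(detections, max_disp, max_gap = 0L) {
  stopifnot(all(c("frame", "x", "y") %in% names(detections)), max_disp > 0)
  det <- dplyr::arrange(tibble::as_tibble(detections), .data$frame)
  det$.det <- seq_len(nrow(det))
  det$.track <- NA_integer_
  frames <- sort(unique(det$frame))
  next_track <- 1L
  by_frame <- split(seq_len(nrow(det)), det$frame)
  # step 1: consecutive-frame greedy linking
  for (fi in seq_along(frames)) {
    rows_f <- by_frame[[as.character(frames[fi])]]
    if (fi == 1L) {
      det$.track[rows_f] <- seq(next_track, length.out = length(rows_f))
      next_track <- next_track + length(rows_f)
      next
    }
    rows_p <- by_frame[[as.character(frames[fi - 1L])]]
    # step 1 links strictly consecutive frames; wholly missing frames
    # break segments here and are bridged by gap closing below
    if (frames[fi] - frames[fi - 1L] == 1L) {
      m <- greedy_match(cbind(det$x[rows_p], det$y[rows_p]),
                        cbind(det$x[rows_f], det$y[rows_f]),
                        max_disp)
      if (nrow(m)) det$.track[rows_f[m[, 2]]] <- det$.track[rows_p[m[, 1]]]
    }
    new <- rows_f[is.na(det$.track[rows_f])]
    det$.track[new] <- seq(next_track, length.out = length(new))
    next_track <- next_track + length(new)
  }
  # step 2: gap closing between segment ends and starts
  if (max_gap > 0L) {
    repeat {
      seg <- det |>
        dplyr::group_by(.data$.track) |>
        dplyr::summarise(
          f_start = min(.data$frame), f_end = max(.data$frame),
          x_start = .data$x[which.min(.data$frame)],
          y_start = .data$y[which.min(.data$frame)],
          x_end = .data$x[which.max(.data$frame)],
          y_end = .data$y[which.max(.data$frame)], .groups = "drop")
      n_seg <- nrow(seg)
      gap <- outer(seg$f_end, seg$f_start, function(e, s) s - e)
      dist2 <- outer(seg$x_end, seg$x_start, "-")^2 +
        outer(seg$y_end, seg$y_start, "-")^2
      ok <- gap >= 2 & gap <= max_gap + 1L & dist2 <= (max_disp * gap)^2
      diag(ok) <- FALSE
      cand <- which(ok, arr.ind = TRUE)
      if (nrow(cand) == 0L) break
      ord <- order(dist2[cand], cand[, 1], cand[, 2])
      best <- cand[ord[1], ]
      from_tr <- seg$.track[best[1]]; to_tr <- seg$.track[best[2]]
      det$.track[det$.track == to_tr] <- from_tr
    }
  }
  det <- dplyr::arrange(det, .data$.track, .data$frame)
  ids <- match(det$.track, unique(det$.track))
  out <- tibble::tibble(track_id = ids, frame = det$frame,
                        x = det$x, y = det$y)
  class(out) <- c("bead_tracks", class(out))
  out
}
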