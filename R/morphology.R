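# Cell-level morphology (area, aspect ratio via threshold + moment
# ellipse), live/dead viability percentages, proliferation curves, and the
# one-way group tests applied to them.

# Otsu-style histogram split on a numeric matrix, on 256 bins.
otsu_threshold <- function(img) {
  v <- as.vector(img)
  rng <- range(v, finite = TRUE)
  if (diff(rng) < .Machine$double.eps) return(rng[1])
  EBImage::otsu(EBImage::Image((v - rng[1]) / diff(rng),
                               dim = dim(img))) * diff(rng) + rng[1]
}

#' Segment cells and measure area and aspect ratio
#'
#' Applies a global threshold (Otsu's histogram split by default, or a
#' user-supplied value), labels connected components, and measures each
#' component's area and second-moment ellipse axes. Components touching the
#' image border are excluded. Touching cells merge into one component at
#' default settings; this is a known limitation of global thresholding.
#'
#' @param image Numeric matrix (e.g. an f-actin channel) or a logical/0-1
#'   mask.
#' @param threshold Numeric threshold; `NULL` (default) uses Otsu's method.
#'   Ignored when `image` is already logical.
#' @param pixel_size Micrometres per pixel.
#' @param min_area Minimum object area in square micrometres (default 4)
#'   to suppress noise specks.
#' @return A `morphology_records` tibble: `object_id`, `x`, `y`, `area`
#'   (square micrometres), `major`, `minor`, `aspect_ratio`,
#'   `orientation`.
#' @export
area_aspect <- function(image, threshold = NULL, pixel_size = 1,
                        min_area = 4) {
  stopifnot(is.matrix(image))
  if (is.logical(image)) {
    mask <- image
  } else {
    thr <- threshold %||% otsu_threshold(image)
    mask <- image > thr
  }
  if (!any(mask)) {
    return(tibble::tibble(object_id = integer(0), x = numeric(0),
                          y = numeric(0), area = numeric(0),
                          major = numeric(0), minor = numeric(0),
                          aspect_ratio = numeric(0),
                          orientation = numeric(0)))
  }
  labels <- EBImage::bwlabel(EBImage::Image(mask * 1, dim = dim(mask)))
  rec <- measure_nucleus_orientation(matrix(as.integer(labels),
                                            nrow(mask), ncol(mask)),
                                     pixel_size = pixel_size,
                                     min_axis_ratio = 1)
  rec <- rec[rec$area >= min_area, ]
  rec <- dplyr::select(rec, "object_id", "x", "y", "area", "major",
                       "minor", "aspect_ratio", "orientation")
  class(rec) <- c("morphology_records", class(rec))
  rec
}

#' Live/dead viability from two fluorescence channels
#'
#' Thresholds the live (green, calcein-type) and dead (red, propidium-type)
#' channels, counts connected components in each, and classifies
#' double-positive objects (a live component whose centroid falls inside
#' the dead mask) as dead — the conservative rule, since dead-stain
#' positivity dominates interpretation. Percentages are normalised against
#' the total count of live plus dead cells.
#'
#' @param green,red Numeric matrices of matching size.
#' @param threshold_green,threshold_red Optional absolute thresholds;
#'   Otsu's split by default.
#' @param pixel_size Micrometres per pixel.
#' @param min_area Minimum object area (square micrometres).
#' @return A list of class `viability_summary`: `n_live`, `n_dead`,
#'   `n_double_positive`, `pct_live`, `pct_dead`, `undefined` (both
#'   channels empty).
#' @export
live_dead <- function(green, red, threshold_green = NULL,
                      threshold_red = NULL, pixel_size = 1, min_area = 4) {
  stopifnot(is.matrix(green), is.matrix(red), all(dim(green) == dim(red)))
  seg <- function(img, thr) {
    if (max(img) - min(img) < .Machine$double.eps) {
      return(tibble::tibble(x = numeric(0), y = numeric(0)))
    }
    recs <- area_aspect(img, threshold = thr, pixel_size = pixel_size,
                        min_area = min_area)
    recs[, c("x", "y")]
  }
  g <- seg(green, threshold_green)
  r <- seg(red, threshold_red)
  red_mask <- if (nrow(r)) {
    thr_r <- threshold_red %||% otsu_threshold(red)
    red > thr_r
  } else matrix(FALSE, nrow(red), ncol(red))
  dbl <- 0L
  if (nrow(g)) {
    gi <- pmax(1L, pmin(nrow(red_mask), round(g$y / pixel_size + 0.5)))
    gj <- pmax(1L, pmin(ncol(red_mask), round(g$x / pixel_size + 0.5)))
    dbl <- sum(red_mask[cbind(gi, gj)])
  }
  n_live <- nrow(g) - dbl
  n_dead <- nrow(r)
  total <- n_live + n_dead
  undefined <- total == 0L
  if (undefined) warning("both channels empty: percentages undefined")
  structure(
    list(n_live = n_live, n_dead = n_dead, n_double_positive = dbl,
         pct_live = if (undefined) NA_real_ else 100 * n_live / total,
         pct_dead = if (undefined) NA_real_ else 100 * n_dead / total,
         undefined = undefined),
    class = "viability_summary")
}

#' @export
print.viability_summary <- function(x, ...) {
  if (x$undefined) cat("<viability_summary> undefined (no cells)\n")
  else cat(sprintf("<viability_summary> live %d (%.1f%%) | dead %d (%.1f%%)\n",
                   x$n_live, x$pct_live, x$n_dead, x$pct_dead))
  invisible(x)
}

#' Proliferation curve normalised to seeding density
#'
#' @param counts Integer vector of cell counts per timepoint.
#' @param n_t0 Seeded cell count at time zero (> 0).
#' @param timepoints Optional vector of timepoint labels/hours.
#' @return A tibble `timepoint`, `count`, `pct` where
#'   `pct = 100 * count / n_t0`.
#' @export
#' @examples
#' proliferation(c(100, 150, 210), 100, c(0, 24, 48))
proliferation <- function(counts, n_t0, timepoints = seq_along(counts)) {
  if (n_t0 <= 0) stop("n_t0 must be positive", call. = FALSE)
  stopifnot(length(timepoints) == length(counts))
  tibble::tibble(timepoint = timepoints, count = counts,
                 pct = 100 * counts / n_t0)
}

#' One-way group tests (ANOVA and Kruskal-Wallis) with post hoc
#'
#' Runs the equal-variance one-way ANOVA F test and the Kruskal-Wallis H
#' test (with tie correction, as implemented by `kruskal.test`), followed
#' by Holm-adjusted pairwise Wilcoxon rank-sum tests.
#'
#' @param values Numeric response vector.
#' @param group Factor or character vector of group labels (each group
#'   needs at least 3 observations).
#' @param alpha Significance level for decisions (default 0.05).
#' @return A list of class `group_tests`: `anova` (tibble: statistic, df,
#'   p), `kruskal` (tibble: statistic, df, p), `posthoc` (tibble of
#'   pairwise Holm-adjusted Wilcoxon p-values with decisions), `alpha`.
#' @export
group_tests <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  stopifnot(length(values) == length(group))
  if (any(table(group) < 3L)) {
    stop("every group needs at least 3 observations", call. = FALSE)
  }
  av <- stats::aov(values ~ group)
  at <- summary(av)[[1]]
  anova_tb <- tibble::tibble(statistic = at$`F value`[1],
                             df1 = at$Df[1], df2 = at$Df[2],
                             p_value = at$`Pr(>F)`[1])
  kw <- stats::kruskal.test(values, group)
  kruskal_tb <- tibble::tibble(statistic = unname(kw$statistic),
                               df = unname(kw$parameter),
                               p_value = kw$p.value)
  pw <- stats::pairwise.wilcox.test(values, group, p.adjust.method = "holm",
                                    exact = FALSE)
  pm <- pw$p.value
  posthoc <- purrr::map_dfr(seq_len(nrow(pm)), function(i) {
    purrr::map_dfr(seq_len(ncol(pm)), function(j) {
      if (is.na(pm[i, j])) return(NULL)
      tibble::tibble(group_a = colnames(pm)[j], group_b = rownames(pm)[i],
                     p_adjusted = pm[i, j],
                     significant = pm[i, j] < alpha)
    })
  })
  structure(list(anova = anova_tb, kruskal = kruskal_tb, posthoc = posthoc,
                 alpha = alpha),
            class = "group_tests")
}

#' @export
print.group_tests <- function(x, ...) {
  cat(sprintf(
    "<group_tests> ANOVA F = %.3f (p = %.3g) | Kruskal-Wallis H = %.3f (p = %.3g)\n",
    x$anova$statistic, x$anova$p_value, x$kruskal$statistic,
    x$kruskal$p_value))
  invisible(x)
}
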