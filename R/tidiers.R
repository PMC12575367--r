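# broom-style tidy()/glance() methods for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @rdname gamma_fit_tidiers
#' @param x A `gamma_fit` object.
#' @param ... Unused.
tidy.gamma_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "sigma"),
                 estimate = c(x$mu, x$sigma),
                 estimate_hist = c(x$mu_hist, x$sigma_hist))
}

#' Tidiers for angular-alignment Gaussian fits
#'
#' @param x A `gamma_fit` object.
#' @param ... Unused.
#' @return `tidy()` returns one row per parameter; `glance()` a one-row
#'   model summary.
#' @name gamma_fit_tidiers
#' @export
glance.gamma_fit <- function(x, ...) {
  tibble::tibble(mu = x$mu, sigma = x$sigma, sigma_wrapped = x$sigma_wrapped,
                 n = x$n, degenerate = x$degenerate)
}

#' @export
#' @rdname alignment_regression_tidiers
tidy.alignment_regression <- function(x, ...) {
  b <- tidy_lm_coefs(x$fit)
  b$term <- c("intercept", "slope")
  b
}

#' Tidiers for orientation-vs-sector regressions
#'
#' @param x An `alignment_regression` object.
#' @param ... Unused.
#' @return `tidy()` returns the coefficient table; `glance()` the fit
#'   summary (slope, intercept, r-squared, number of sectors).
#' @name alignment_regression_tidiers
#' @export
glance.alignment_regression <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n_sectors = x$n_sectors)
}

tidy_lm_coefs <- function(fit) {
  cf <- summary(fit)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, 1],
                 std_error = cf[, 2], statistic = cf[, 3],
                 p_value = cf[, 4])
}

#' @export
#' @rdname kuiper_tidiers
tidy.kuiper_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 p_asymptotic = x$p_asymptotic, n_a = x$n_a, n_b = x$n_b,
                 n_perm = x$n_perm)
}

#' Tidiers for Kuiper two-sample tests
#'
#' @param x A `kuiper_test` object.
#' @param ... Unused.
#' @name kuiper_tidiers
#' @export
glance.kuiper_test <- function(x, ...) tidy.kuiper_test(x)

#' @export
#' @rdname speed_fit_tidiers
tidy.speed_fit <- function(x, ...) {
  tibble::tibble(term = c("meanlog", "sdlog", "peak_speed"),
                 estimate = c(x$meanlog, x$sdlog, x$peak_speed))
}

#' Tidiers for lognormal speed fits
#'
#' @param x A `speed_fit` object.
#' @param ... Unused.
#' @name speed_fit_tidiers
#' @export
glance.speed_fit <- function(x, ...) {
  tibble::tibble(meanlog = x$meanlog, sdlog = x$sdlog,
                 peak_speed = x$peak_speed, n_tracks = x$n_tracks,
                 degenerate = x$degenerate)
}

#' @export
#' @rdname stretch_tidiers
tidy.stretch_decomposition <- function(x, ...) {
  tibble::tibble(
    term = c("rotation_deg", "lambda1", "lambda2", "max_shear",
             "equibiaxiality", "offdiag_norm", "det_F"),
    estimate = c(x$rotation_deg, x$principal_stretches, x$max_shear,
                 x$equibiaxiality, x$offdiag_norm, x$det_F))
}

#' Tidier for polar decompositions
#'
#' @param x A `stretch_decomposition` object.
#' @param ... Unused.
#' @name stretch_tidiers
#' @export
glance.stretch_decomposition <- function(x, ...) {
  tibble::tibble(rotation_deg = x$rotation_deg,
                 lambda1 = x$principal_stretches[1],
                 lambda2 = x$principal_stretches[2],
                 max_shear = x$max_shear, physical = x$physical)
}

#' @export
#' @rdname group_tests_tidiers
tidy.group_tests <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$anova, test = "anova", .before = 1) |>
      dplyr::rename(df = "df1") |> dplyr::select(-"df2"),
    dplyr::mutate(x$kruskal, test = "kruskal_wallis", .before = 1))
}

#' Tidiers for one-way group tests
#'
#' @param x A `group_tests` object.
#' @param ... Unused.
#' @name group_tests_tidiers
#' @export
glance.group_tests <- function(x, ...) {
  tibble::tibble(anova_F = x$anova$statistic, anova_p = x$anova$p_value,
                 kruskal_H = x$kruskal$statistic,
                 kruskal_p = x$kruskal$p_value,
                 n_significant_pairs = sum(x$posthoc$significant))
}
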