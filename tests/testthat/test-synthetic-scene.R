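test_that("pattern orientation equals the polar angle, axially reduced", {
  cfg <- small_cfg()
  ctr <- cfg$pillar_center
  spec <- pattern_spec(ctr, 12, cfg$pillar_radius)
  # due east -> 0, due north (up, smaller storage y) -> 90
  expect_equal(pattern_orientation_at(spec, ctr[1] + 50, ctr[2]), 0)
  expect_equal(pattern_orientation_at(spec, ctr[1], ctr[2] - 50), 90)
  expect_equal(pattern_orientation_at(spec, ctr[1] - 50, ctr[2]), 0)   # west, axial
  expect_equal(pattern_orientation_at(spec, ctr[1], ctr[2] + 50), 90)  # south, axial
  # exact identity against atan2 on random points
  set.seed(1)
  ang <- runif(300, 0, 2 * pi)
  rr <- runif(300, 12.5, cfg$pillar_radius - 0.5)
  x <- ctr[1] + rr * cos(ang); y <- ctr[2] - rr * sin(ang)
  got <- pattern_orientation_at(spec, x, y)
  want <- (ang * 180 / pi) %% 180
  expect_lt(max(abs(wrap_axial_diff(got - want))), 1e-9)
  # outside annulus -> NA
  expect_true(is.na(pattern_orientation_at(spec, ctr[1] + 5, ctr[2])))
})

test_that("rasterised ridge coverage matches brute-force high-res count", {
  cfg <- scene_config(seed = 1, pixel_size = 2, image_shape = c(128L, 128L))
  spec <- pattern_spec(cfg$pillar_center, 15, cfg$pillar_radius)
  pat <- make_pattern(spec, cfg)
  frac <- mean(pat$mask, na.rm = TRUE)
  # oracle: rasterise at 10x finer pixels and count
  fine <- scene_config(seed = 1, pixel_size = 0.2,
                       image_shape = c(1280L, 1280L))
  pat10 <- make_pattern(pattern_spec(fine$pillar_center * 1, 15,
                                     cfg$pillar_radius), fine)
  frac10 <- mean(pat10$mask, na.rm = TRUE)
  expect_lt(abs(frac - frac10), 0.01)
  # equal angular ridge/groove split puts coverage at one half
  expect_lt(abs(frac10 - 0.5), 0.005)
  # stripe widths within bounds at ring edges
  rings <- pat$rings
  widths_lo <- 2 * pi * rings$edges[-length(rings$edges)] / rings$counts
  widths_hi <- 2 * pi * rings$edges[-1] / rings$counts
  expect_true(all(widths_lo >= spec$groove_width_min - 1e-9))
  expect_true(all(widths_hi <= spec$ridge_width_max + 1e-9))
})

test_that("infeasible pattern widths raise a configuration error", {
  expect_error(pattern_spec(c(0, 0), 10, 50, ridge_width_max = 3,
                            groove_width_min = 2), "infeasible")
})

test_that("prescribed fields evaluate displacement and F analytically", {
  cfg <- small_cfg()
  ctr <- cfg$pillar_center
  # affine: u = (A - I) p
  fA <- generate_field(affine_spec(diag(c(1.1, 1.1))), cfg)
  expect_equal(as.numeric(field_displacement(fA, ctr + c(10, 0))), c(1, 0))
  expect_equal(field_F(fA, ctr + c(33, -12))[[1]], diag(c(1.1, 1.1)))
  # linear radial profile is isotropic affine
  fL <- generate_field(field_spec("radial_profile", g = function(r) 0.1 * r,
                                  gprime = function(r) rep(0.1, length(r))),
                       cfg)
  for (p in list(c(40, 10), c(-25, 60), c(0.01, 0))) {
    expect_equal(field_F(fL, ctr + p)[[1]], diag(c(1.1, 1.1)),
                 tolerance = 1e-8)
  }
  # quadratic profile at r = R/2: F_polar = diag(1 + eps, 1 + eps/2)
  R <- cfg$pillar_radius
  fQ <- generate_field(quadratic_radial_spec(R, eps = 0.1), cfg)
  FQ <- field_F(fQ, ctr + c(R / 2, 0))[[1]]  # east: polar frame = Cartesian
  expect_equal(FQ, diag(c(1.1, 1.05)), tolerance = 1e-9)
  # r = 0 singularity resolved to the g'(0) limit
  expect_equal(field_F(fQ, ctr)[[1]], diag(2), tolerance = 1e-9)
  # radial fields are symmetric (rotation-free) everywhere
  set.seed(3)
  pts <- cbind(runif(50, -R, R), runif(50, -R, R))
  Fs <- field_F(fQ, sweep(pts, 2, -ctr))
  asym <- vapply(Fs, function(Fi) abs(Fi[1, 2] - Fi[2, 1]), numeric(1))
  expect_lt(max(asym), 1e-12)
})

test_that("bead tracks advect exactly and reproduce under a fixed seed", {
  cfg <- small_cfg(seed = 11)
  A <- diag(c(1.08, 1.08))
  fld <- generate_field(affine_spec(A, n_frames = 3L), cfg)
  tr <- simulate_bead_tracks(100, fld, 0, cfg)
  p0 <- tr[tr$frame == 0, ]
  p2 <- tr[tr$frame == 2, ]
  want <- sweep(sweep(as.matrix(p0[, c("x", "y")]), 2, cfg$pillar_center) %*%
                  t(A), 2, cfg$pillar_center, "+")
  expect_equal(as.matrix(p2[, c("x", "y")]), want, ignore_attr = TRUE,
               tolerance = 1e-12)
  tr2 <- simulate_bead_tracks(100, fld, 0, cfg)
  expect_identical(tr, tr2)
})

test_that("noisy bead displacement RMS matches its closed-form expectation", {
  cfg <- small_cfg(seed = 21)
  R <- cfg$pillar_radius
  fld <- generate_field(quadratic_radial_spec(R, 0.1, n_frames = 11L), cfg)
  sd0 <- 0.1
  tr <- simulate_bead_tracks(500, fld, sd0, cfg)
  truth <- attr(tr, "truth")
  for (f in c(5L, 10L)) {
    d <- tr[tr$frame == f, c("x", "y")]
    d0 <- tr[tr$frame == 0, c("x", "y")]
    emp <- sqrt(mean((d$x - d0$x)^2 + (d$y - d0$y)^2))
    ut <- truth[truth$frame == f, c("x", "y")]
    ut0 <- truth[truth$frame == 0, c("x", "y")]
    ana <- sqrt(mean((ut$x - ut0$x)^2 + (ut$y - ut0$y)^2) + 4 * sd0^2)
    expect_lt(abs(emp - ana) / ana, 0.02)
  }
})

test_that("cell population carries pattern orientation plus wrapped noise", {
  cfg <- small_cfg(seed = 5)
  spec <- pattern_spec(cfg$pillar_center, 0.1 * cfg$pillar_radius,
                       cfg$pillar_radius)
  cells0 <- simulate_cell_population(spec, 200, 0, cfg)
  expect_lt(max(abs(wrap_axial_diff(cells0$orientation -
                                      cells0$true_orientation))), 1e-9)
  # dispersion recovery within 10% of 8 degrees at n = 500
  cells <- simulate_cell_population(spec, 500, 8, cfg)
  resid <- wrap_axial_diff(cells$orientation - cells$true_orientation)
  expect_lt(abs(axial_sd(resid) - 8) / 8, 0.10)
})

test_that("rendered nuclei re-measure to their generating orientation", {
  cfg <- scene_config(seed = 2, pixel_size = 1, image_shape = c(200L, 200L))
  cells <- tibble::tibble(cell_id = 1:3, x = c(50, 120, 80),
                          y = c(60, 140, 150),
                          orientation = c(37, 120, 5))
  lab <- render_nuclei_labels(cells, cfg, semi_major = 14, semi_minor = 5)
  m <- measure_nucleus_orientation(lab, pixel_size = 1)
  m <- m[order(m$object_id), ]
  expect_equal(nrow(m), 3L)
  expect_lt(max(abs(wrap_axial_diff(m$orientation - cells$orientation))), 1)
})

test_that("migration walks hit their concentration limits", {
  cfg <- small_cfg(seed = 7)
  # kappa -> infinity: straight lines, zero turning angles
  sp <- migration_spec("flat_undeformed", turning_concentration = 1e9,
                       drift_weight = 0)
  tr <- simulate_migration(sp, 10, 15, cfg)
  ss <- step_and_turning_angles(tr)
  expect_lt(max(abs(ss$turning$angle)), 1e-6)
  # kappa = 0: uniform turning angles; Rayleigh non-significant in most seeds
  sp0 <- migration_spec("flat_undeformed", turning_concentration = 0,
                        drift_weight = 0)
  rej <- vapply(1:100, function(s) {
    trs <- simulate_migration(sp0, 20, 12, cfg, seed = 1000 + s)
    rayleigh_p(step_and_turning_angles(trs)$turning$angle) < 0.05
  }, logical(1))
  expect_gte(mean(!rej), 0.94)
})

test_that("per-step lognormal speeds are recovered by the estimator", {
  cfg <- small_cfg(seed = 13)
  sp <- migration_spec("flat_undeformed",
                       speed_lognormal = c(meanlog = log(0.5), sdlog = 0.3),
                       turning_concentration = 0, drift_weight = 0)
  tr <- simulate_migration(sp, 25, 42, cfg)  # ~1000 steps
  fit <- speed_stats(tr, per = "step")
  expect_lt(abs(fit$meanlog - log(0.5)) / abs(log(0.5)), 0.05)
  expect_lt(abs(fit$sdlog - 0.3) / 0.3, 0.05)
})

test_that("migration presets order persistence and speed as intended", {
  pre <- radialign:::migration_presets()
  k <- vapply(pre, function(p) p$turning_concentration, numeric(1))
  expect_gt(min(k[c("flat_deformed", "patterned_deformed")]),
            max(k[c("flat_undeformed", "patterned_undeformed")]))
  expect_equal(names(which.max(k)), "patterned_deformed")
  ml <- vapply(pre, function(p) p$speed_lognormal[["meanlog"]], numeric(1))
  sl <- vapply(pre, function(p) p$speed_lognormal[["sdlog"]], numeric(1))
  expect_equal(names(which.max(ml)), "patterned_deformed")
  expect_equal(names(which.min(sl)), "patterned_deformed")
})

test_that("rendered stacks are deterministic and empty scenes stay empty", {
  cfg <- scene_config(seed = 3, pixel_size = 1, image_shape = c(64L, 64L))
  tr <- tibble::tibble(track_id = 1L, frame = 0L, x = 30, y = 30)
  s1 <- render_bead_stack(tr, cfg, spot_sigma_px = 1.5)
  s2 <- render_bead_stack(tr, cfg, spot_sigma_px = 1.5)
  expect_identical(s1, s2)
  # zero spots -> background-only frame, no detections downstream
  empty <- tibble::tibble(track_id = integer(0), frame = integer(0),
                          x = numeric(0), y = numeric(0))
  st <- render_bead_stack(empty, cfg, spot_sigma_px = 1.5, peak = 500,
                          background = 10, read_noise = 1, frames = 0L)
  d <- suppressWarnings(detect_spots(st[[1]], 1.5))
  expect_equal(nrow(d), 0L)
  expect_warning(render_bead_stack(empty, cfg, spot_sigma_px = 1.5),
                 "no frames")
  expect_warning(render_bead_stack(tr, cfg, spot_sigma_px = 0.3),
                 "sub-Nyquist")
})

test_that("write_scene writes the documented artefact set", {
  dir <- tempfile("scene_")
  cfg <- scene_config(seed = 1, pixel_size = 1, image_shape = c(64L, 64L))
  tr <- tibble::tibble(track_id = c(1L, 1L), frame = 0:1, x = c(1, 2),
                       y = c(3, 4))
  cells <- tibble::tibble(cell_id = 1L, x = 10, y = 12, orientation = 30)
  write_scene(dir, cfg, tracks = tr, cells = cells)
  expect_true(all(file.exists(file.path(
    dir, c("tracks.csv", "cells.csv", "scene.yaml")))))
  rt <- read_tracks(file.path(dir, "tracks.csv"))
  expect_equal(rt$x, tr$x)
  sc <- yaml::read_yaml(file.path(dir, "scene.yaml"))
  expect_equal(sc$scene$seed, 1L)
})
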