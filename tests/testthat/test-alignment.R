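test_that("sector partition indexes points and boundaries as documented", {
  p <- sector_partition(c(0, 0), 10, r_edges = c(0, 150))
  expect_equal(p$n_sectors, 36L)
  # polar angle 195 deg (math frame): storage y is flipped
  loc <- locate_in_partition(p, cos(195 * pi / 180) * 100,
                             -sin(195 * pi / 180) * 100)
  expect_equal(loc$sector, 19L)
  expect_equal(loc$sector_orientation, 15)
  # a point exactly on a boundary joins the higher-index sector
  loc_b <- locate_in_partition(p, cos(10 * pi / 180) * 100,
                               -sin(10 * pi / 180) * 100)
  expect_equal(loc_b$sector, 1L)
  expect_error(sector_partition(c(0, 0), 7), "divide 360")
})

test_that("gamma follows its wrap rules and definition", {
  p <- sector_partition(c(0, 0), 10, r_edges = c(10, 150))
  # orientation 45 in the sector at orientation 40 -> gamma 5
  rec <- tibble::tibble(x = cos(deg(42)) * 100, y = -sin(deg(42)) * 100,
                        orientation = 45)
  gt <- angular_alignment(rec, p)
  expect_equal(gt$sector_orientation, 45)  # sector 4 bisector
  rec2 <- tibble::tibble(x = cos(deg(41)) * 100, y = -sin(deg(41)) * 100,
                         orientation = 45)
  gt2 <- angular_alignment(rec2, p)
  expect_equal(gt2$gamma, 0)
  # axial wrap: orientation 2 vs reference 178 -> gamma 4, not -176
  p2 <- sector_partition(c(0, 0), 4, r_edges = c(10, 150))
  rec3 <- tibble::tibble(x = cos(deg(178)) * 100, y = -sin(deg(178)) * 100,
                         orientation = 2)
  gt3 <- angular_alignment(rec3, p2)
  expect_equal(gt3$sector_orientation, 178)
  expect_equal(gt3$gamma, 4)
  # records outside the annulus are excluded and counted
  rec4 <- tibble::tibble(x = c(5, 100), y = c(0, 0), orientation = c(0, 0))
  gt4 <- angular_alignment(rec4, p)
  expect_equal(nrow(gt4), 1L)
  expect_equal(attr(gt4, "n_excluded"), 1L)
})

test_that("zero-noise populations give zero gamma against the local
           reference and bounded gamma against sector bisectors", {
  cfg <- small_cfg(seed = 18)
  spec <- pattern_spec(cfg$pillar_center, 15, cfg$pillar_radius)
  part <- sector_partition(cfg$pillar_center, 10,
                           r_edges = c(15, cfg$pillar_radius))
  cells <- simulate_cell_population(spec, 300, 0, cfg)
  g_local <- angular_alignment(cells, part, reference = "local")
  expect_lt(max(abs(g_local$gamma)), 1e-9)
  g_sector <- angular_alignment(cells, part, reference = "sector")
  expect_lte(max(abs(g_sector$gamma)), 5)
  expect_lt(abs(mean(g_sector$gamma)), 1)
})

test_that("gamma fitting is consistent, equivariant and guarded", {
  set.seed(31)
  # estimator consistency over repeated draws
  mus <- sigmas <- numeric(10)
  for (i in 1:10) {
    g <- rnorm(500, 0, 8)
    f <- fit_gamma(g)
    mus[i] <- f$mu; sigmas[i] <- f$sigma
  }
  expect_lt(max(abs(mus)), 1)
  expect_lt(max(abs(sigmas - 8) / 8), 0.15)
  # shift equivariance
  g <- rnorm(200, 0, 5)
  expect_equal(fit_gamma(g + 10)$mu, fit_gamma(g)$mu + 10,
               tolerance = 1e-10)
  # degenerate input flagged
  fd <- fit_gamma(rep(0, 50))
  expect_true(fd$degenerate)
  expect_equal(fd$mu, 0)
  expect_equal(fd$sigma, 0)
  expect_error(fit_gamma(rnorm(5)), "refused")
  # tidy/glance round out the broom surface
  f8 <- fit_gamma(rnorm(100, 0, 8))
  expect_named(glance(f8),
               c("mu", "sigma", "sigma_wrapped", "n", "degenerate"))
  expect_equal(nrow(tidy(f8)), 2L)
})

test_that("orientation regression finds slope 1 for followers, 0 for
           fixed-orientation populations", {
  cfg <- small_cfg(seed = 19)
  spec <- pattern_spec(cfg$pillar_center, 15, cfg$pillar_radius)
  part <- sector_partition(cfg$pillar_center, 10,
                           r_edges = c(15, cfg$pillar_radius))
  cells <- simulate_cell_population(spec, 540, 8, cfg)
  reg <- orientation_regression(angular_alignment(cells, part))
  expect_lt(abs(reg$slope - 1), 0.05)
  expect_gt(reg$r_squared, 0.95)
  # population ignoring the pattern: constant lab-frame orientation
  fixed <- cells
  fixed$orientation <- 90
  reg0 <- orientation_regression(angular_alignment(fixed, part))
  expect_lt(abs(reg0$slope), 0.1)
  gt0 <- angular_alignment(fixed, part)
  # near-uniform gamma: sd close to uniform on [-90, 90)
  expect_gt(sd(gt0$gamma), 40)
})

test_that("r-band analysis is stable under shared noise and detects an
           injected outer-band bias", {
  cfg <- small_cfg(seed = 20)
  R <- cfg$pillar_radius
  spec <- pattern_spec(cfg$pillar_center, 0.1 * R, R)
  part <- sector_partition(cfg$pillar_center, 10,
                           r_edges = seq(0.1 * R, R, length.out = 4))
  cells <- simulate_cell_population(spec, 900, 8, cfg)
  tb <- alignment_by_rband(cells, part)
  expect_true(all(tb$status == "ok"))
  expect_lt(max(tb$mu) - min(tb$mu), 3)  # within +-1.5 deg of each other
  # +10 deg bias injected in the outer band only
  r_outer_edge <- part$r_edges[3]
  biased <- simulate_cell_population(
    spec, 900, 8, cfg, bias_fun = function(r) ifelse(r >= r_outer_edge, 10, 0))
  tb2 <- alignment_by_rband(biased, part)
  expect_lt(abs(tb2$mu[1]), 2.5)
  expect_gt(tb2$mu[3], 7)
  # an empty band reports insufficient data
  part_far <- sector_partition(cfg$pillar_center, 10,
                               r_edges = c(0.02 * R, 0.05 * R, R))
  tb3 <- alignment_by_rband(
    simulate_cell_population(spec, 50, 8, cfg), part_far)
  expect_equal(tb3$status[1], "insufficient")
})

test_that("gamma multiset is equivariant under rotation of the scene", {
  cfg <- small_cfg(seed = 22)
  R <- cfg$pillar_radius
  spec <- pattern_spec(cfg$pillar_center, 0.1 * R, R)
  part <- sector_partition(cfg$pillar_center, 10, r_edges = c(0.1 * R, R))
  cells <- simulate_cell_population(spec, 200, 8, cfg)
  gt <- angular_alignment(cells, part)
  # rotate centroids and orientations by a multiple of the sector width
  phi <- 30
  ctr <- cfg$pillar_center
  Rm <- rotation_matrix(phi)
  # math rotation by +phi maps storage coords via conjugated matrix
  dx <- cells$x - ctr[1]; dy <- -(cells$y - ctr[2])
  rx <- dx * cos(deg(phi)) - dy * sin(deg(phi))
  ry <- dx * sin(deg(phi)) + dy * cos(deg(phi))
  rot <- cells
  rot$x <- ctr[1] + rx; rot$y <- ctr[2] - ry
  rot$orientation <- wrap_axial(cells$orientation + phi)
  gt_rot <- angular_alignment(rot, part)
  expect_equal(sort(gt_rot$gamma), sort(gt$gamma), tolerance = 1e-9)
})

test_that("nucleus moment ellipses exclude circles and border objects", {
  cfg <- scene_config(seed = 2, pixel_size = 1, image_shape = c(120L, 120L))
  cells <- tibble::tibble(cell_id = 1:2, x = c(40, 80), y = c(40, 80),
                          orientation = c(37, 0))
  lab <- render_nuclei_labels(cells, cfg, semi_major = 12, semi_minor = 4)
  # add a circle (no orientation) and a border-touching blob
  lab[60:70, 1:6] <- 90L
  xs <- matrix(seq_len(120) - 0.5, 120, 120, byrow = TRUE)
  ys <- t(xs)
  lab[(xs - 100)^2 + (ys - 20)^2 <= 36] <- 91L
  m <- measure_nucleus_orientation(lab, pixel_size = 1)
  expect_false(90 %in% m$object_id)  # border excluded entirely
  circ <- m[m$object_id == 91, ]
  expect_false(circ$reliable)
  good <- m[m$object_id %in% 1:2, ]
  expect_true(all(good$reliable))
  expect_true(all(good$orientation >= 0 & good$orientation < 180))
  expect_lt(max(abs(wrap_axial_diff(good$orientation -
                                      cells$orientation))), 1)
})

test_that("structure-tensor dominant orientation resolves gratings", {
  for (phi in seq(0, 165, by = 15)) {
    est <- measure_dominant_orientation(grating_tile(phi))
    expect_false(est$isotropic)
    expect_lt(abs(wrap_axial_diff(est$orientation - phi)), 1)
  }
  # 0 and 180 degree gratings are the same axial stimulus
  e0 <- measure_dominant_orientation(grating_tile(0))
  e180 <- measure_dominant_orientation(grating_tile(180))
  expect_lt(abs(wrap_axial_diff(e0$orientation - e180$orientation)), 1e-6)
  # white noise is flagged isotropic
  set.seed(99)
  noise <- matrix(runif(96 * 96), 96, 96)
  en <- measure_dominant_orientation(noise)
  expect_true(en$isotropic)
  expect_true(is.na(en$orientation))
})
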