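test_that("displacement_field matches affine truth and bookkeeping rules", {
  cfg <- small_cfg(seed = 10)
  A <- diag(c(1.1, 1.1))
  fld <- generate_field(affine_spec(A), cfg)
  tr <- simulate_bead_tracks(50, fld, 0, cfg)
  d <- displacement_field(tr, 0, 1)
  p0 <- cbind(d$x0, d$y0)
  want <- sweep(p0, 2, cfg$pillar_center) %*% t(A - diag(2))
  expect_equal(cbind(d$ux, d$uy), want, ignore_attr = TRUE,
               tolerance = 1e-12)
  # same frame twice: all-zero field
  d0 <- displacement_field(tr, 1, 1)
  expect_true(all(abs(c(d0$ux, d0$uy)) < 1e-14))
  # tracks missing the target frame are excluded and counted
  tr_cut <- tr[!(tr$track_id <= 5 & tr$frame == 1), ]
  d2 <- displacement_field(tr_cut, 0, 1)
  expect_equal(nrow(d2), 45L)
  expect_equal(attr(d2, "n_dropped"), 5L)
  expect_error(displacement_field(tr[tr$track_id <= 2, ], 0, 1),
               "underdetermined")
})

test_that("estimate_F is exact for affine fields with noiseless beads", {
  cfg <- small_cfg(seed = 12)
  A <- matrix(c(1.07, 0.02, -0.01, 1.12), 2, 2, byrow = TRUE)
  fld <- generate_field(affine_spec(A), cfg)
  tr <- simulate_bead_tracks(1200, fld, 0, cfg)
  fmap <- estimate_F(displacement_field(tr, 0, 1), cfg$pillar_center,
                     cfg$pillar_radius)
  ok <- !is.na(fmap$F_xx)
  expect_gt(sum(ok), 0.9 * nrow(fmap))
  err <- pmax(abs(fmap$F_xx[ok] - A[1, 1]), abs(fmap$F_xy[ok] - A[1, 2]),
              abs(fmap$F_yx[ok] - A[2, 1]), abs(fmap$F_yy[ok] - A[2, 2]))
  expect_lt(max(err), 1e-9)
  expect_true(all(fmap$n_support[ok] >= 3))
  expect_true(all(fmap$rms_residual[ok] < 1e-9))
})

test_that("F estimation is frame-invariant: translation and rotation", {
  cfg <- small_cfg(seed = 14)
  R <- cfg$pillar_radius
  A <- diag(c(1.15, 1.05))  # anisotropic so conjugation is non-trivial
  fld <- generate_field(affine_spec(A), cfg)
  tr <- simulate_bead_tracks(800, fld, 0, cfg)
  d <- displacement_field(tr, 0, 1)
  fmap <- estimate_F(d, cfg$pillar_center, R)
  # translation of the whole scene leaves F unchanged
  d_t <- d
  d_t$x0 <- d_t$x0 + 123.4; d_t$y0 <- d_t$y0 - 56.7
  fmap_t <- estimate_F(d_t, cfg$pillar_center + c(123.4, -56.7), R)
  ok <- !is.na(fmap$F_xx) & !is.na(fmap_t$F_xx)
  expect_lt(max(abs(fmap$F_xx[ok] - fmap_t$F_xx[ok]),
                abs(fmap$F_xy[ok] - fmap_t$F_xy[ok]),
                abs(fmap$F_yx[ok] - fmap_t$F_yx[ok]),
                abs(fmap$F_yy[ok] - fmap_t$F_yy[ok])), 1e-9)
  # rotating the scene by phi conjugates F by R(phi)
  phi <- 30
  Rm <- rotation_matrix(phi)
  ctr <- cfg$pillar_center
  p_rot <- sweep(sweep(cbind(d$x0, d$y0), 2, ctr) %*% t(Rm), 2, ctr, "+")
  u_rot <- cbind(d$ux, d$uy) %*% t(Rm)
  d_r <- d
  d_r$x0 <- p_rot[, 1]; d_r$y0 <- p_rot[, 2]
  d_r$ux <- u_rot[, 1]; d_r$uy <- u_rot[, 2]
  fmap_r <- estimate_F(d_r, ctr, R)
  # for an affine field both estimates are exact, so every reported node
  # must carry exactly the conjugated tensor
  want <- Rm %*% A %*% t(Rm)
  okr <- !is.na(fmap_r$F_xx)
  expect_gt(sum(okr), 100)
  expect_lt(max(abs(fmap_r$F_xx[okr] - want[1, 1]),
                abs(fmap_r$F_xy[okr] - want[1, 2]),
                abs(fmap_r$F_yx[okr] - want[2, 1]),
                abs(fmap_r$F_yy[okr] - want[2, 2])), 1e-9)
})

test_that("polar decomposition separates rotation from stretch", {
  d0 <- decompose_F(diag(c(1.1, 1.1)))
  expect_equal(d0$rotation_deg, 0)
  expect_equal(d0$principal_stretches, c(1.1, 1.1))
  expect_equal(d0$max_shear, 0)
  dr <- decompose_F(rotation_matrix(5) %*% diag(c(1.1, 1.1)))
  expect_equal(abs(dr$rotation_deg), 5, tolerance = 1e-9)
  expect_equal(dr$principal_stretches, c(1.1, 1.1), tolerance = 1e-12)
  ds <- decompose_F(diag(c(1.2, 1.05)))
  expect_equal(ds$max_shear, 0.075)
  expect_equal(ds$equibiaxiality, 1.05 / 1.2)
  # F = R U reconstruction to numerical precision
  F1 <- rotation_matrix(-12) %*% matrix(c(1.15, 0.03, 0.03, 1.02), 2, 2)
  dd <- decompose_F(F1)
  expect_lt(max(abs(dd$R %*% dd$U - F1)), 1e-10)
  expect_warning(decompose_F(matrix(c(1, 0, 0, -1), 2, 2)), "non-physical")
})

test_that("displacement_map interpolates and masks outside the hull", {
  set.seed(2)
  n <- 80
  d <- tibble::tibble(track_id = 1:n,
                      x0 = runif(n, 0, 100), y0 = runif(n, 0, 100),
                      ux = 0.6, uy = -0.8)  # uniform magnitude 1
  class(d) <- c("displacement_field", class(d))
  m <- displacement_map(d, grid_spacing = 5)
  inside <- !is.na(m$magnitude)
  expect_gt(sum(inside), 50)
  expect_lt(max(abs(m$magnitude[inside] - 1)), 1e-9)
  # corners outside the convex hull are masked
  expect_true(any(!inside))
  # radial field: interpolated magnitude grows with radius
  cfg <- small_cfg(seed = 15)
  R <- cfg$pillar_radius
  fld <- generate_field(quadratic_radial_spec(R, 0.1), cfg)
  tr <- simulate_bead_tracks(300, fld, 0, cfg)
  dr <- displacement_field(tr, 0, 1)
  mr <- displacement_map(dr, grid_spacing = R / 10)
  rr <- sqrt((mr$x - cfg$pillar_center[1])^2 +
               (mr$y - cfg$pillar_center[2])^2)
  keep <- !is.na(mr$magnitude) & rr < R
  cor_rm <- cor(rr[keep], mr$magnitude[keep])
  expect_gt(cor_rm, 0.95)
})

test_that("radial strain bands recover uniform and graded strain", {
  cfg <- small_cfg(seed = 16)
  R <- cfg$pillar_radius
  # uniform 10% biaxial strain: every band at 0.10
  fldU <- generate_field(field_spec("radial_profile",
                                    g = function(r) 0.1 * r,
                                    gprime = function(r) rep(0.1, length(r)),
                                    n_frames = 2L),
                         cfg)
  trU <- simulate_bead_tracks(600, fldU, 0, cfg)
  fmapU <- estimate_F(displacement_field(trU, 0, 1), cfg$pillar_center, R)
  bandsU <- radial_strain_profile(fmapU, n_bands = 3)
  expect_equal(bandsU$mean_strain, rep(0.1, 3), tolerance = 1e-6)
  # quadratic profile: band means strictly increase with radius
  fldQ <- generate_field(quadratic_radial_spec(R, 0.1), cfg)
  trQ <- simulate_bead_tracks(2000, fldQ, 0, cfg)
  fmapQ <- estimate_F(displacement_field(trQ, 0, 1), cfg$pillar_center, R)
  bandsQ <- radial_strain_profile(fmapQ, n_bands = 3)
  expect_true(all(diff(bandsQ$mean_strain) > 0))
  # n_bands = 1: overall mean matches the node-averaged analytic strain
  bands1 <- radial_strain_profile(fmapQ, n_bands = 1)
  rq <- sqrt((fmapQ$x - cfg$pillar_center[1])^2 +
               (fmapQ$y - cfg$pillar_center[2])^2)
  okq <- !is.na(fmapQ$F_xx)
  ana <- mean(0.15 * rq[okq] / R)
  expect_lt(abs(bands1$mean_strain - ana) / ana, 0.02)
})

test_that("F standard error shrinks like one over sqrt(n) beads", {
  cfg0 <- small_cfg()
  R <- cfg0$pillar_radius
  fld_spec <- affine_spec(diag(c(1.1, 1.1)))
  se_at <- function(n_beads) {
    vals <- vapply(1:6, function(s) {
      cfg <- small_cfg(seed = 300 + s)
      fld <- generate_field(fld_spec, cfg)
      tr <- simulate_bead_tracks(n_beads, fld, 0.1, cfg)
      fmap <- estimate_F(displacement_field(tr, 0, 1), cfg$pillar_center, R,
                         neighborhood_radius = 30)
      i <- which(!is.na(fmap$F_xx))
      i <- i[which.min((fmap$x[i] - cfg$pillar_center[1])^2 +
                         (fmap$y[i] - cfg$pillar_center[2])^2)]
      fmap$F_xx[i]
    }, numeric(1))
    stats::sd(vals)
  }
  se <- vapply(c(50, 200, 800), se_at, numeric(1))
  # errors should fall roughly fourfold over a 16-fold n increase
  expect_lt(se[3], se[1] / 2)
})
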