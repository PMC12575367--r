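# radialign

Quantification toolkit for mechanobiology imaging experiments in which
cardiomyocytes (or any adherent cells) are cultured on a **radially
micropatterned elastic membrane** under **equibiaxial stretch**. The package
covers the three quantification chains such experiments need, end to end,
plus a synthetic-scene generator that produces every input with known ground
truth:

1. **Membrane deformation from fiducial beads.** Beads embedded in the
   membrane are detected (Laplacian-of-Gaussian), linked into tracks
   (greedy nearest-neighbour + gap closing), and the planar displacement
   field u(X) between a reference and a deformed frame is fitted locally by
   weighted least squares to estimate the deformation-gradient map
   F(X) = ∂x/∂X on a grid. The polar decomposition F = R·U separates rigid
   rotation from the stretch tensor U, whose eigenvalues λ₁ ≥ λ₂ are the
   principal stretches: a pure equibiaxial stretch has R ≈ I and
   λ₁ ≈ λ₂, i.e. F diagonal with no shear. Radial strain profiles in
   annular bands expose the deformation gradient that grows from the pillar
   centre outward.
2. **Contact-guidance alignment on the radial pattern.** The pillar is
   partitioned into 10° θ-sectors; each nucleus (second-moment ellipse) or
   actin tile (structure tensor) contributes an axial orientation, and the
   angular alignment γ = orientation − sector orientation (wrapped to
   [−90°, 90°)) is fitted with a Gaussian — aligned populations give mean
   μ ≈ 0 — while the per-sector mean orientation regressed on sector
   orientation gives slope ≈ 1.
3. **Migration persistence.** Nuclei tracked over an hour yield step
   directions (rose/windrose diagrams), turning angles (wrapped differences
   of consecutive step directions), lognormal speed fits whose density peak
   is the representative velocity, and condition comparisons with the
   two-sample **Kuiper test** (rotation-invariant circular analogue of
   Kolmogorov–Smirnov, V = D⁺ + D⁻) under Holm correction. Persistent
   migration shows turning angles concentrated at 0°.

Everything is tidyverse-native: functions take data frames and return
tibbles, fitted objects have broom-style `tidy()`/`glance()` methods, and
each result type has a `plot_*()`/`autoplot()` ggplot2 visualisation.

## Worked example

A full synthetic experiment — a pillar of radius R ≈ 150 µm with the radial
displacement profile u(r) = 0.1 r²/R (10 % strain scale, growing with r),
500 beads at 0.1 µm localisation noise, a 500-cell pattern-following
population with 8° angular noise, and four migration conditions:

```r
library(radialign)

cfg   <- scene_config(seed = 42)
R     <- cfg$pillar_radius
field <- generate_field(
  field_spec("radial_profile", g = function(r) 0.1 * r^2 / R,
             gprime = function(r) 0.2 * r / R, n_frames = 11L), cfg)

tracks <- simulate_bead_tracks(500, field, noise_sd = 0.1, cfg)
disp   <- displacement_field(tracks, frame_ref = 0, frame_target = 10)
fmap   <- estimate_F(disp, cfg$pillar_center, R, neighborhood_radius = 16)
radial_strain_profile(fmap, n_bands = 3, dispfield = disp)
#>    band  r_lo  r_hi mean_strain sd_strain n_nodes mean_disp
#> 1     1   0    49.9      0.0344    0.0148      78     0.961
#> 2     2  49.9  99.8      0.0767    0.0168     233     4.17
#> 3     3  99.8 150.       0.129     0.0182     381    16.1
```

The recovered band strains (3.4 %, 7.7 %, 12.9 %) reproduce the imposed
radial gradient (analytic node means 3.3 %, 7.8 %, 12.7 %), and the mean
displacement grows from ~1 µm at the centre to ~16 µm at the rim.

```r
cells <- simulate_cell_population(
  pattern_spec(cfg$pillar_center, r_inner = 15, r_outer = R), 500, 8, cfg)
part  <- sector_partition(cfg$pillar_center, theta_width = 10,
                          r_edges = seq(15, R, length.out = 4))
gt    <- angular_alignment(cells, part)
fit_gamma(gt)
#> <gamma_fit> n = 500 | MLE mu = 0.36 deg, sigma = 8.24 deg
orientation_regression(gt)
#> <alignment_regression> slope = 0.996, intercept = 0.70 deg, r^2 = 0.998 (36 sectors)
```

μ ≈ 0 and slope ≈ 1: the population follows the radial pattern.

```r
conds <- c("flat_undeformed", "patterned_undeformed",
           "flat_deformed", "patterned_deformed")
trajs <- purrr::set_names(conds) |>
  purrr::map(~ simulate_migration(migration_spec(.x), 40, 61, cfg))
pan <- condition_panel(trajs, n_perm = 199, seed = 1)
pan$per_condition[, c("condition", "persistence", "peak_speed")]
#>   condition            persistence peak_speed
#> 1 flat_undeformed            0.238      0.456
#> 2 patterned_undeformed       0.331      0.505
#> 3 flat_deformed              0.632      0.596
#> 4 patterned_deformed         0.846      0.732
```

Persistence (mean resultant length of turning angles) and the lognormal
speed peak both rise from undeformed to deformed conditions, with the
patterned + deformed condition highest; all six pairwise Kuiper tests are
significant after Holm correction (adjusted p = 0.015).

`run_demo("full", seed = 1, out_dir = "demo_out")` runs the three chains in
one call and writes CSV/JSON summaries and figures;
`validate_suite(seed = 1)` returns a pass/fail table of the package's
structural invariants. A thin command-line wrapper over the same functions
is at `inst/cli/radialign.R`.

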