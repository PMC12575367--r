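---
title: "Methods: deformation mapping, radial alignment and migration statistics"
author: "radialign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deformation mapping, radial alignment and migration statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radialign)
```

This vignette explains the models and procedures the package implements,
the conventions and tunable parameters that matter, what the synthetic
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## Setting and conventions

The experiments the package quantifies place cells on a thin elastic
(PDMS) membrane whose central circular *pillar* is stretched
equibiaxially; a radial ridge/groove micropattern on the pillar aligns
cells with the local stretch direction. Three imaging assays feed the
analysis: fiducial beads in the membrane imaged before/during stretch
(one frame per minute over ten minutes, ramp then hold), fixed nuclei and
f-actin channels for alignment, and nuclei tracked once per minute over an
hour for migration.

Conventions used everywhere:

* lengths in micrometres, times in minutes, angles in degrees;
* angles are counter-clockwise positive from the +x axis, in the
  mathematical (y-up) frame. Pixel storage has y increasing downward, so a
  single y-flip is applied wherever an angle is derived from pixel
  coordinates; this is the only place the two frames meet;
* directional data (headings, turning angles) wrap to (−180°, 180°];
  axial data (orientations, defined modulo 180°) wrap to [0°, 180°), and
  axial *differences* to [−90°, 90°). The last wrap is the only one under
  which a perfectly aligned population has differences concentrated at 0°.

## Deformation-gradient mapping

The displacement field is sampled at bead positions: a track table gives
reference positions `X_i` (frame `r`) and displacements
`u_i = x_i − X_i` (frame `t`). At each node of a square grid clipped to
the pillar disc (default spacing R/20), the local affine model

u(X) ≈ a + (F − I)(X − node)

is fitted by weighted least squares with a Gaussian kernel of bandwidth
half the neighbourhood radius. Weighted least squares on an affine model
is *exact* for affine fields regardless of bead layout, which anchors the
estimator's unit tests; for curved fields the leading error is a
smoothing bias growing with the squared neighbourhood radius and with
field curvature, so the neighbourhood radius is the resolution/variance
trade-off the user controls. Defaults: `neighborhood_radius = 3 ×
grid_spacing`; for sparse beads (hundreds over a ~300 µm field) we use a
neighbourhood comparable to the mean bead spacing (≈16 µm at 500 beads),
which keeps the inner-band bias of a quadratic test profile below a few
per cent while leaving enough support per node.

Nodes are masked, never extrapolated, when (a) fewer than 3 beads fall in
the neighbourhood, (b) the weighted normal matrix is numerically singular
(collinear support), or (c) the weighted standard deviation of support
positions along their least-spread axis falls below 0.15 × neighbourhood
radius. Rule (c) exists because *nearly* collinear supports pass a rank
test yet have unbounded leverage: under localisation noise they produce
arbitrarily wild local gradients, and a handful of such nodes visibly
biased band-averaged strain in early experiments.

The polar decomposition F = R·U (computed from the SVD, with det R = +1
enforced) reports the rotation angle, principal stretches λ₁ ≥ λ₂, the
maximum shear (λ₁ − λ₂)/2 and the equibiaxiality index λ₂/λ₁. A pure
equibiaxial stretch is the regime R = I, λ₁ = λ₂, off-diagonals of F
zero; an injected rigid rotation is the negative control, and the
estimator recovers a 5° rotation within half a degree at 0.1 µm noise.

**Strain per node** is the mean normal strain tr(F)/2 − 1. For
rotation-free fields this equals the mean principal stretch minus one,
mean(λ₁, λ₂) − 1; we deliberately use the trace form because it is linear
in F: the singular values are convex in F, so under zero-mean estimation
noise mean(λ₁, λ₂) is biased upward, which distorted the low-strain inner
band at realistic bead densities. The trace form has no such bias, at the
cost of slightly undercounting stretch when a genuine rotation is present
(second order in the rotation angle, negligible here). Radial strain
profiles average nodes within equal-width annuli (default 3 bands).

The displacement magnitude map uses inverse-distance-weighted
interpolation masked outside the convex hull of the beads — a display
product, not an estimator; no quantity is read back from it.

## Spot detection and linking

Bead/nucleus detection is a scale-normalised Laplacian-of-Gaussian filter
matched to the spot radius, local maxima above a robust threshold
(median + 8 × MAD of the response, floored at 2 % of the peak response so
numerically flat backgrounds yield nothing), non-maximum suppression
within one sigma (a spot centred between pixels otherwise yields a 2×2
plateau of equal maxima), then sub-pixel refinement by intensity-weighted
centroid in a ±2σ window after subtracting the window minimum. On
rendered high-SNR spots the centroid lands within 0.02 px of ground
truth.

Linking is deliberately the simple two-step scheme: (1) between strictly
consecutive frames, candidate pairs within `max_disp` are accepted
greedily in global cost order (ties broken by lowest index, so linking is
deterministic); (2) gap closing joins a segment end to a later segment
start when the frame gap is ≤ `max_gap` and the distance ≤ `max_disp` per
skipped interval, repeatedly taking the cheapest join. A full linear
assignment problem solver would be marginally more accurate in dense
scenes; the greedy scheme is transparent, dependency-free and exact on
the bead densities used here (tracks recovered verbatim in the noiseless
oracle test).

## Radial alignment

The pillar is partitioned into θ-sectors of 10° (36 sectors) and annular
bands. A sector's orientation is the axial angle of its bisecting radius;
a point exactly on a boundary belongs to the higher-index sector (the
tie is measure-zero but must be deterministic). Object orientations come
from two estimators:

* **per-object moment ellipse** (nuclei): second central moments of the
  pixel support, plus the 1/12-pixel variance of the square pixel
  footprint; orientation is the major-axis angle, and objects with axis
  ratio < 1.05 or touching the border are excluded as orientation-less;
* **structure tensor** (actin tiles): gradients from 2-D
  Gaussian-derivative filters — chosen over central differences because
  their frequency response is isotropic, removing an orientation bias of
  up to ~2° on fine gratings — tensor smoothing at σ = 2 px, and an
  energy-and-coherence-weighted axial histogram of the stripe orientation
  (perpendicular to the gradient). The dominant orientation is the
  smoothed histogram mode refined by the weighted axial mean within two
  bins of the peak; tiles with energy-weighted mean coherence < 0.35 are
  flagged isotropic (oriented textures score ≳0.95, white noise ≲0.3).

The angular alignment γ of a record is the axial difference between its
orientation and a reference at its centroid, with two references
available. `reference = "sector"` (default) uses the containing sector's
bisector, the definition used in sector-based workflows; note that under
it even a perfectly radial population spreads γ uniformly over ±5°
(half the sector width), so the fitted σ carries a floor of
width²/12 ≈ (2.9°)². `reference = "local"` uses the exact polar angle of
the centroid, so γ isolates angular noise alone; parameter-recovery tests
use it. Both give μ ≈ 0 for aligned populations.

γ is fitted with a Gaussian by maximum likelihood on the raw values
(primary) and by least squares on the binned histogram (reported for
parity with histogram-reading workflows); a wrapped-dispersion estimate
from the axial resultant length is included as a cross-check — for
σ ≤ 20° the wrapping correction is negligible, which is why the plain
normal fit is retained. The orientation regression takes per-sector axial
mean orientations, unwraps each to the branch nearest its sector's
orientation (the mod-180 ambiguity makes a naive regression meaningless),
and fits ordinary least squares against sector orientation; sectors with
fewer than `n_min = 5` objects (a choice, stated as such) or a vanishing
axial resultant are dropped. Slope ≈ 1 with μ ≈ 0 jointly indicate
pattern following; a fixed lab-frame orientation gives slope ≈ 0 and
near-uniform γ. The whole pipeline repeats per annular band so a radial
strain gradient can be checked for any effect on alignment.

## Migration statistics

Step directions are atan2 angles of consecutive displacements; turning
angles are wrapped differences of consecutive step directions within a
track (directional, period 360°). Steps shorter than `min_step` (default
0; recommended twice the localisation noise) are dropped from angle
statistics rather than given an arbitrary direction. Rose histograms bin
either every step direction (default, the richer distribution) or one net
direction per track; both modes are labelled in the output because
published rose plots rarely state which was used.

Per-track mean speed is path length over elapsed time; the lognormal fit
is the closed-form MLE on the log scale, and the reported representative
velocity is the density peak exp(μ_log − σ_log²), matching workflows that
read the mode off a fitted lognormal. `per = "step"` fits instantaneous
step speeds instead — the scale on which the generator draws speeds, and
the scale on which parameter recovery is tested.

The two-sample Kuiper statistic V = D⁺ + D⁻ is computed as the range of
the cumulative difference of the two empirical distribution functions
over the circularly ordered pooled sample, in integer arithmetic
(counts cross-scaled by the opposite sample size), which makes V
*exactly* invariant under common rotation and within-sample relabelling —
the two symmetries asserted to machine identity in the tests. Tied values
are evaluated only after a whole tie group, so identical samples give
V = 0. The p-value is by label permutation with a fixed seed (primary,
valid at any n); because V is discrete, the plain permutation p is
systematically conservative (measured null rejection ≈ 2.6 % at nominal
5 %), so the reported `p_value` is the mid-p variant — permutations tied
with the observed V count half — restoring ≈ 4.5 % empirical size, with
the conservative value kept alongside as `p_conservative`. The asymptotic
tail formula is reported for groups of at least 20. Pairwise condition
comparisons apply Holm's step-down correction.

## The synthetic scene

The generator produces every input with known ground truth under one root
seed (per-component child streams; identical seeds give byte-identical
outputs):

* **pattern**: radial stripes whose local orientation is exactly the polar
  angle mod 180°; because arc width grows with radius, the stripe count
  doubles whenever a ridge would exceed 5 µm, keeping widths within the
  2–5 µm bounds (this doubling rule needs max/min ≥ 2 and is one
  admissible realisation of the sub-sectoring, which the source imagery
  does not dimension further);
* **fields**: affine (F = A everywhere) or radial profile u = g(r)·r̂
  with analytic F = diag(1 + g′, 1 + g/r) in the polar frame and the
  g′(0) limit at the centre; a linear ramp over frames emulates the
  pressure ramp and hold;
* **beads**: uniform over the imaged membrane (beads are embedded
  throughout the PDMS, not only in the pillar; restricting them to the
  pillar disc starves rim nodes of one-sided support), Lagrangian
  advection plus i.i.d. Gaussian localisation noise per frame;
* **cells**: centroids uniform on the annulus, orientation = local
  pattern orientation + wrapped normal noise (an optional radius-dependent
  bias injects band-specific misalignment for negative controls);
* **migration**: persistent random walk — lognormal per-step speeds, von
  Mises turning angles (Best–Fisher sampler; κ = 0 is uniform), optional
  relaxation toward a common drift direction (the collective motion seen
  without deformation) or toward the local outward radial direction
  (deformed conditions), reflecting image boundaries so no track is
  truncated. The four condition presets encode the qualitative findings
  being emulated: κ rises from ~0.3–0.5 (undeformed) to 1.5 and 2.5
  (deformed flat/patterned), and the patterned-deformed speed
  distribution is the highest and narrowest (meanlog log 0.7, sdlog 0.3);
  where the source reports no numeric value these are fixed, realistic
  choices for slow cardiac cells (~0.4–0.8 µm/min) and are not revisited;
* **rendering**: Gaussian spots with Poisson photon noise plus Gaussian
  read noise; nuclei as filled ellipses in a label image.

What the generator does **not** emulate: optical blur beyond the spot
model, uneven illumination, cell shape change, division, death and
crossing tracks, membrane mechanics (fields are prescribed, not solved),
and out-of-plane displacement — the z-row/column of F is out of scope by
design. Passing tests therefore certify the estimators on data satisfying
their model assumptions plus realistic noise; they do not certify
segmentation robustness on difficult real imagery.

## Problem sizes and reproducibility

Test and demo problem sizes are chosen so the full suite and the
acceptance script each run in well under their practical budgets on one
CPU: noiseless oracle checks use a few hundred beads to 60 000 beads (the
"dense" regime where the band estimator's bias floor is below 0.5 %),
noisy recovery uses 500 beads × 20 seeds, alignment recovery 500 cells ×
20 seeds per noise level, Kuiper calibration 500 null replicates at 199
permutations, and power 200 seeds. Every stochastic step takes an
explicit seed; `run_demo()` writes the full configuration next to its
outputs, and rerunning with the same seed reproduces `summary.json`
byte-identically.

## Known limitations

* Greedy linking can swap identities in dense, fast scenes; `max_disp`
  should stay below half the typical inter-object spacing.
* The sector-reference γ carries the sector-width quantisation floor in
  σ (not in μ); use the local reference for dispersion estimates.
* The structure-tensor estimator reports a single dominant orientation
  per tile; crossing fibre populations are flagged only through higher
  dispersion.
* Global thresholding merges touching cells; the morphology interface
  accepts externally produced label images so a stronger segmenter can be
  substituted.
* The deformation-gradient chain is strictly 2-D.
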