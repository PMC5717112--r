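---
title: "Haemodynamic analysis of 4D flow MRI: models, parameters and validation"
author: "aortaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haemodynamic analysis of 4D flow MRI: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortaflow)
```

## What this package computes

Time-resolved phase-contrast MRI with three-directional velocity encoding
("4D flow") measures a velocity vector in every voxel of a 3D volume at
every cardiac phase. From such a measurement of the ascending aorta the
pipeline derives, at the peak-systolic time frame:

* **peak velocity** — the maximum speed in a region of interest,
* **mean velocity** — the spatial mean of speed over the segmented lumen,
* **wall shear stress (WSS)** — the tangential viscous traction the blood
  exerts on the vessel wall, in Pa,
* **viscous energy loss (EL)** — the rate at which the flow dissipates
  kinetic energy through viscosity, integrated over the lumen, in mW,

and, for two patient cohorts (here: recipients of stented versus
stentless aortic bioprostheses), builds a shared vessel geometry in which
per-voxel Mann-Whitney tests localize where the cohorts differ.

Because no patient data are distributed, every stage is developed and
validated against analytic tube-flow phantoms with closed-form ground
truth; the phantom generator is a first-class, tested module.

## The phantom generator

`phantom_config()` encodes the study conditions of a clinical acquisition:
2.0 × 1.7 × 2.2 mm³ voxels, 18 cardiac phases at 40 ms, peak velocities of
2–2.5 m/s downstream of a bioprosthetic valve, and a venc (velocity
encoding limit) of 1.5 m/s per direction. The tube defaults to radius
R = 10 mm and length L = 100 mm, commensurate with an adult ascending
aorta.

Three velocity profiles are available:

* **poiseuille** — the steady parabolic profile
  $v(r) = v_{max}(1 - r^2/R^2)$. This is the oracle: at the wall
  $\tau = 2\mu v_{max}/R$ and the total dissipation over length $L$ is
  $\dot E = 2\pi \mu L v_{max}^2$ (0.64 Pa and 2.01 mW for
  $v_{max}=1$ m/s, $\mu = 3.2$ cP, R = 10 mm, L = 100 mm).
* **womersley** — the Bessel-function solution for pulsatile tube flow,
  used only for time-resolved realism; no closed-form WSS/EL is asserted
  for it. The Womersley number is computed with blood density
  1060 kg/m³.
* **eccentric_jet** — a parabolic core of radius R/2 displaced radially by
  `jet_offset`, with zero co-flow. One parameter (the offset) controls the
  central-versus-outer-lumen contrast that distinguishes the two cohorts;
  a stentless-like valve produces a central jet, a stented-like valve an
  eccentric one.

The temporal envelope is a systolic pulse peaking (exactly 1) at frame 5
over a 0.05 diastolic floor — chosen so that peak-systole detection has an
unambiguous truth and so that late frames carry almost no flow, which is
what makes the last time frame usable for eddy-current estimation.

`corrupt_phantom()` applies, in acquisition order: Gaussian velocity noise
(default sd 0.05 m/s, a realistic noise floor for a venc-limited
acquisition), a stationary first-order eddy-current offset plane, and venc
wrapping $v \mapsto v - 2\,\mathrm{venc}\cdot\mathrm{round}(v/2\,\mathrm{venc})$.
All randomness derives from the configuration seed.

`generate_cohorts()` draws two cohorts (default n = 14 per group, matching
the study design the pipeline reproduces) differing only in the planted
effect — by default a 4 mm jet-offset difference — plus per-subject rigid
jitter (rotations up to 5°, translations up to 3 mm) so that atlas
registration is genuinely exercised. Between-subject variability (jet
offset sd 0.3 mm, peak velocity sd 0.05 m/s) keeps subjects distinct
without drowning the planted effect.

What the phantoms do **not** emulate: MR signal formation (magnitude is a
binary vessel/background contrast with a 0.05 floor, not Bloch-equation
physics), Maxwell phase errors (their correction needs sequence gradient
waveforms that are not available, so neither corruption nor correction is
modeled), turbulence, valve leaflets, or wall motion. Passing tests
therefore demonstrate correctness of the numerical machinery on smooth
laminar fields, not robustness to every clinical artifact.

## Pre-processing

**Eddy currents.** Static tissue is identified as voxels with above-floor
magnitude and temporal velocity standard deviation below 0.05 m/s (a
conventional heuristic; both thresholds are arguments). A first-order
polynomial (constant + linear in x, y, z) is fitted per velocity direction
to the static-tissue velocities of the last time frame and subtracted from
all frames. If fewer than 100 static voxels exist the correction is
skipped with a warning. Slow near-wall flow that passes the static screen
biases the fitted plane by well under 1 mm/s in practice; the tests bound
this.

**Velocity unwrapping.** The default algorithm is quality-guided region
growing: starting from the voxel of smallest speed, voxels are merged in
order of ascending wrapped difference to an already-unwrapped 6-neighbor,
each shifted by the multiple of 2 venc matching that neighbor; afterwards
the global branch is anchored by subtracting the median wrap count, since
growth determines the field only up to one global multiple of 2 venc. This
recovers any wrap pattern exactly as long as true neighbor-to-neighbor
differences stay below venc. A simpler neighborhood-median algorithm
(shift voxels that deviate from their 3×3×3 median by more than venc,
iterated) is available behind the same interface; it repairs isolated
wraps but was found to be structurally unable to detect extended wrapped
regions — inside a solid wrapped jet core every voxel agrees with its own
neighborhood median, so the detector never fires. That failure mode, not
speed, motivated the region-growing default.

**Noise masking.** Voxels are kept when their time-averaged magnitude
reaches a fraction (default 0.1) of the 99th-percentile time-averaged
magnitude; velocities outside are zeroed.

**PC-MRA.** Per frame the magnitude image is multiplied by the velocity
magnitude; the frames are then averaged. The mean (not the sum) keeps the
units stable across acquisitions with different frame counts.

## Segmentation and the vessel wall

`segment_vessel()` thresholds the time-averaged PC-MRA at a fraction of
its 99th-percentile intensity, keeps the largest 26-connected component
and applies one morphological closing pass. It is a deterministic
surrogate for the expert manual segmentation used clinically; masks may
also be supplied from file. Because the threshold is defined relative to
the 99th percentile, the top percentile of voxels always survives — an
"empty segmentation" error can only arise via the axial `keep_band` (the
anatomical annulus-to-brachiocephalic restriction, not computable on
phantoms). The pipeline default threshold is 0.02: on PC-MRA data the
background noise floor sits around half a percent of the 99th-percentile
intensity while slow near-wall flow sits well above 2%, so this choice
preserves most of the near-wall shell without admitting background.
When the magnitude-based noise mask is available (it always is in the
pipeline), the thresholded component additionally grows, iteratively,
into that magnitude support: the velocity-weighted PC-MRA inevitably
under-represents the slowest near-wall voxels, and the magnitude image is
what tells a human reader they are still lumen. This makes the
segmentation nearly independent of the noise level — on phantoms the
grown mask matches the analytic lumen exactly with or without noise —
which matters because both the WSS wall placement and the boundary-heavy
EL integral are sensitive to losing the outer shell.

`extract_wall()` derives the wall representation:

* wall points originate at inside voxels with at least one outside
  6-neighbor;
* outward normals are the negated, normalized gradient of a
  Gaussian-smoothed (σ = 1 voxel per axis) inside-indicator;
* each point is projected onto the 0.5 level of that smoothed indicator
  along its normal (bisection, shift capped at one voxel), so points sit
  on the lumen surface rather than at voxel centers. This matters for
  WSS: the method forces the velocity to zero at the wall point, and a
  point up to one voxel inside the lumen — where flow is still
  0.1–0.2 $v_{max}$ — would inflate the wall slope by 15% or more;
* the local radius is the maximum of the anisotropic Euclidean distance
  transform along the inward-normal ray (the maximal inscribed distance
  at the medial point of that ray) — robust for curved vessels, and
  insensitive to the sampling span precisely because the wall point sits
  on the surface;
* each point carries a surface patch area (the voxel cross-sections
  projected onto the tangent plane), used for surface-fraction statistics.

## Wall shear stress

Per wall point the axis system is rotated so the local z-axis aligns with
the outward normal. The two in-plane velocity components are sampled by
trilinear interpolation at three equidistant points along the inward
normal spanning one local radius: the wall point itself (velocity forced
to zero), depth R/2 and depth R. The unique interpolating quadratic
through three points — the only "spline" a 3-point fit admits — gives the
wall-normal derivative analytically at the wall; multiplying by the
dynamic viscosity (3.2 cP unless overridden) and rotating back yields the
3D WSS vector, tangential by construction (any numerical normal component
is discarded). For a locally parabolic profile the quadratic is exact up
to interpolation error; on the default grid the mean |WSS| of the
Poiseuille phantom is within 4% of $2\mu v_{max}/R$, within ~2% at half
spacing.

Wall points whose sample ray leaves the mask are flagged and excluded
from the map mean, as are points with dominantly through-plane flow
(|v·n| > 0.5 |v| at depth R/2): blood does not cross the vessel wall, so
such points are the open inlet/outlet cut faces of the segmentation (the
phantom's end caps), not wall. Without this exclusion the cut faces bias
the phantom's mean |WSS| several percent low.

## Viscous energy loss

First-order spatial gradients of the three velocity components are taken
by central differences inside the mask, falling back to one-sided
differences at the mask boundary (second-order one-sided where two
interior neighbors exist — exact for the quadratic profiles WSS assumes —
else first-order). Gradients never straddle the mask boundary, so the
zero background cannot contaminate them. The dissipation function

$$\Phi = 2\left(v_{x,x}^2 + v_{y,y}^2 + v_{z,z}^2\right)
 + (v_{x,y}+v_{y,x})^2 + (v_{x,z}+v_{z,x})^2 + (v_{y,z}+v_{z,y})^2
 - \tfrac{2}{3}(\nabla\!\cdot\!v)^2$$

is evaluated per voxel (floored at zero), and
$\dot E = \mu \sum \Phi\, \Delta V$, reported in mW. The compressibility
term is retained by default because measured fields are not
divergence-free; for analytic phantoms it is numerically negligible, and
it can be disabled. Method descriptions in this literature are often
silent on whether the summation over the segmentation is multiplied by
the voxel volume; it must be, since only then is the result an energy
rate in mW rather than a resolution-dependent quantity.

## The shared geometry and cohort maps

The reference mask is the subject of median lumen volume (ties toward the
lower index, which makes the choice invariant to subject order). Every
mask is rigidly registered to it by Nelder-Mead over translations and
rotations about the mask centroid, maximizing a symmetric soft overlap:
reference intensity at the transformed moving points *plus* moving
intensity at the back-transformed reference points. The symmetric form is
essential for the affine stage — a one-sided overlap is maximized by
collapsing the moving mask into the reference interior. A small
minimal-displacement penalty (5×10⁻⁴ per mm² of mean squared point
displacement) selects the least-motion member of the solution family;
mask overlap is blind to spin about the axis of a near-tubular vessel, and
unregularized optimization wanders freely in that flat valley. For the
same reason, registration accuracy is quantified by the identifiable
components — tube-axis tilt and mean surface displacement — rather than
raw Euler angles.

The shared mask keeps voxels covered by at least `inclusion_fraction`
(default 0.6) of the registered masks. Each subject is then registered
affinely (initialized from its rigid transform, one registration reused
for all of its maps) and its peak-systolic speed volume, wall |WSS| and
EL density are pulled onto the shared voxels and wall points by
nearest-neighbour interpolation; shared locations farther than two voxels
from any subject sample are missing. Subjects whose affine Dice falls
below 0.5 are excluded and recorded. Cohort means are defined where at
least two subjects contribute.

## Voxel-wise statistics

`mann_whitney_u()` computes U by rank summation with midranks. For
tie-free samples with pooled size ≤ 16 the two-sided p comes from the
exact null permutation distribution; otherwise a normal approximation
with tie correction and continuity correction is used. Identical pooled
values yield a flagged p = 1. At every shared location where both cohorts
have at least `min_n = 7` non-missing values (a cutoff that keeps the
per-location tests away from degenerate sample sizes), the test yields a
p-value and a direction (+1 when the stentless-like cohort is larger).
No multiple-testing correction is applied by default, matching the
uncorrected p-value maps the pipeline reproduces; a Benjamini-Hochberg
option exists because the per-voxel family is large. Significance
fractions report the percentage of testable locations significant in each
direction — per volume for velocity and EL, per wall surface for WSS.

With 14-versus-14 cohorts the pooled size is 28, so the per-voxel tests
run on the approximation path; its true size at α = 0.05 is 4.4% rather
than 5.0% (the exact test's attainable size is 4.97%), which is the kind
of mild conservatism the calibration tests account for by judging the
empirical rate against Monte-Carlo variation across seeds.

`compare_group_summaries()` reproduces the conventional table: per metric
the median and IQR per cohort and the shared two-sided Mann-Whitney p.

## Numerical choices and degenerate inputs

* Frames are 1-based; peak-systole ties break toward the earlier frame.
* The 3×3×3 median filter uses reflected edge padding; it is applied once,
  to the peak-systolic frame, before all four metrics. On coarse grids it
  bites: a tube of 3-voxel radius loses ~25% of its peak to the filter,
  a 5-voxel radius ~7%. Tests acknowledge this instead of pretending the
  filter is free.
* The Euclidean distance transform is the lower-envelope (parabola)
  algorithm applied separably with anisotropic spacing, property-tested
  against brute force.
* Single-voxel or thin (< 3 voxel) mask structures flag their wall points;
  flagged points are excluded from map means.
* All pipeline randomness (registration multi-starts, cohort draws)
  derives from one master seed; subject seeds are derived deterministically
  below 2³¹.
* Problem sizes used by the test-suite and the acceptance script — the
  default 24×28×50 grid, one half-spacing refinement (48×56×102), 50×1000
  null calibration tests and one 14-versus-14 cohort comparison — were
  chosen so the full validation completes on a single CPU in well under
  half an hour while still exercising every stage at the study's stated
  resolution.

## Known limitations

* The threshold segmentation is a surrogate: it reproduces expert masks
  only to the extent that PC-MRA contrast does; anatomical landmarks
  (annulus, brachiocephalic artery) must be supplied as an axial band.
* WSS accuracy inherits the resolution dependence of the underlying
  method; values at 2 mm resolution underestimate by a few percent even
  on ideal data, consistent with the published behavior of
  inward-normal WSS estimators.
* Mask-based registration cannot recover axial spin of a near-cylindrical
  vessel (a gauge freedom); value maps are insensitive to it for
  axisymmetric flow, and the regularizer keeps it small regardless.
* The exact Mann-Whitney path is limited to pooled sizes ≤ 16; cohort
  comparisons at n = 14 + 14 rely on the tie-corrected normal
  approximation, which is mildly conservative.
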