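# aortaflow

4D flow MRI haemodynamics of the ascending aorta, as an R package: from
raw three-directional velocity volumes to wall shear stress, viscous
energy loss and voxel-wise cohort statistics.

## The problem

Time-resolved phase-contrast MRI with three-directional velocity encoding
("4D flow MRI") measures a velocity vector in every voxel of a 3D volume
at every cardiac phase. Clinically it is used to ask whether different
aortic valve prostheses — for example stented versus stentless
bioprostheses — leave different flow signatures in the ascending aorta.
Answering that requires a chain of numerical steps that are easy to get
subtly wrong: phase-offset correction, venc unwrapping, angiographic
(PC-MRA) segmentation, wall shear stress estimation from coarse voxel
data, viscous dissipation integrals, inter-subject registration into a
shared geometry, and per-voxel nonparametric testing.

`aortaflow` implements that chain end to end, and — because clinical
cohorts cannot be redistributed — ships an analytic flow-phantom
generator whose closed forms validate every stage.

## The quantities

At the peak-systolic frame (the frame maximizing mean speed in the
segmentation, median-filtered 3×3×3), over the segmented lumen:

* **peak velocity** `max |v|` (m/s) and **mean velocity** `mean |v|` (m/s);
* **wall shear stress**: per wall point the axes are rotated so z aligns
  with the outward normal n; the in-plane velocity components are sampled
  at three equidistant points along the inward normal spanning one local
  radius R (zero at the wall, depths R/2 and R); the interpolating
  quadratic gives the wall derivative, and
  `τ = μ ∂v_t/∂n |_wall` (Pa) with μ = 3.2 cP;
* **viscous energy loss** from the dissipation function
  `Φ = 2(v_x,x² + v_y,y² + v_z,z²) + (v_x,y+v_y,x)² + (v_x,z+v_z,x)² +
  (v_y,z+v_z,y)² − (2/3)(∇·v)²`,
  `EL = μ Σ Φ ΔV` (mW);
* **cohort maps**: all subject masks are rigidly registered to a
  median-volume reference, a shared mask is built by consensus, each
  subject's velocity/WSS/EL values are affinely mapped in by
  nearest-neighbour interpolation, and a Mann-Whitney U test runs at every
  shared location (exact permutation p for small tie-free samples, tie-
  and continuity-corrected normal approximation otherwise), yielding
  p-value maps and the percentage of volume/wall surface significant in
  each direction at α = 0.05.

For the steady parabolic (Poiseuille) phantom the oracles are
`τ = 2 μ v_max / R` and `EL = 2 π μ L v_max²`.

## A worked example

```r
library(aortaflow)

# a clean analytic phantom at clinical resolution:
# 2.0 x 1.7 x 2.2 mm voxels, 18 frames @ 40 ms, R = 10 mm, L = 100 mm
ph <- generate_phantom(phantom_config(v_max = 1, noise_sigma = 0))

mask <- ph$truth$mask
summ <- summarize_hemodynamics(ph$velocity, mask)
summ
#> # A tibble: 1 × 6
#>   peak_velocity mean_velocity mean_wss energy_loss peak_frame  mu_cP
#>           <dbl>         <dbl>    <dbl>       <dbl>      <int>  <dbl>
#> 1         0.925         0.465    0.623        2.11          5    3.2
```

Reading the row: the parabolic profile peaks at 1 m/s, and the 3×3×3
median filter plus voxel discretization trims the measured peak to
0.93 m/s; the spatial mean of a parabola is half its peak (0.47 after
filtering); the wall shear stress estimate 0.623 Pa sits within 3% of the
closed form 2μv_max/R = 0.64 Pa; the energy loss 2.11 mW is within 5% of
2πμLv_max² = 2.01 mW; frame 5 is where the systolic envelope peaks.

A full two-cohort comparison on synthetic cohorts (stented-like eccentric
jets versus stentless-like central jets, 14 subjects each):

```r
coh <- generate_cohorts(14, base = phantom_config(),
                        effect = c(jet_offset = 4, v_max = 0), seed = 11)
rep <- run_cohort_comparison(pipeline_config(), coh)
rep$group_table          # Table-style medians, IQRs, Mann-Whitney p
rep$fractions            # % of volume / wall surface significant per direction
glance(rep$pmaps$velocity)
plot_pvalue_mip(rep$pmaps$velocity, rep$shared)  # red/blue significance MIP
```

A thin command-line front end wraps the same functions
(`inst/cli/aortaflow.R`, verbs `simulate`, `subject`, `cohort`), reading
its thresholds from a YAML config.

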