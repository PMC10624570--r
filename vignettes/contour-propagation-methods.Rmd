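---
title: "Comparing contour-propagation strategies on synthetic pelvic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing contour-propagation strategies on synthetic pelvic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In daily MR-guided radiotherapy of prostate cancer, a new MRI is acquired at
every treatment session (fraction) and the planning delineations — bladder,
rectum, clinical target volume (CTV) — must be transferred to that day's
anatomy before the plan can be adapted. Several strategies exist for this
transfer, and they fail in different ways:

* **Rigid copying** transfers the planning contours unchanged (after rigid
  alignment). It is exact when nothing moved and degrades with any
  deformation or filling change.
* **Deformable image registration (DIR)**, here a multi-resolution cubic
  B-spline model, estimates a smooth dense displacement field (DDF) between
  the planning and fraction image and warps the contours with it.
* **Segmentation networks** (a baseline model BM trained on many patients,
  or a patient-specific model PSM fine-tuned on one patient's augmented
  planning image) delineate the fraction image directly, ignoring the
  planning contours at inference time.
* **Displacement networks (DDFM)** predict the DDF with a 3D U-Net whose
  3-channel output feeds a spatial transformer layer (STL), so the planning
  contours are warped rather than re-segmented.

The scientific question this package operationalizes is *which strategy
survives which kind of inter-fraction change*. The central phenomenon is
organ volume change: a bladder that fills between planning and treatment
days undergoes a transformation that is not a smooth small-displacement
warp, so any method whose output is a regularized displacement field
(classical DIR and DDFMs alike) is structurally unable to express it, while
a voxel classifier is indifferent to it. The package reproduces this
mechanism end-to-end on synthetic cohorts.

## The phantom and what it does (and does not) emulate

Clinical MR-Linac images are not publicly available, so every stage runs on
a parametric pelvic phantom (`anatomy_params()`, `make_cohort()`):

* bladder and CTV as ellipsoids, rectum as a curved capped tube, with
  pairwise-disjoint rendered masks;
* piecewise-constant tissue intensities (bright fluid-filled bladder, darker
  rectum, intermediate prostate) plus additive Gaussian noise, a smooth
  additive background texture, and an optional multiplicative bias field —
  a qualitative stand-in for low-field bSSFP contrast;
* inter-patient variability through jittered geometry, and inter-fraction
  variation through re-rendered anatomy: organ volume factors drawn from
  configurable ranges, a small random rigid CTV shift, and a smooth
  background deformation.

Two choices deserve emphasis. First, fraction masks are **re-rendered from
deformed geometric primitives, never produced by warping the planning
masks**; otherwise organ volume change would by construction be expressible
by a displacement field and the central failure mode would vanish from the
ground truth. Second, the **background texture is anchored to the patient**
(constant across that patient's days): without any soft-tissue
heterogeneity the displacement between two images is unobservable over most
of the volume, and no image-driven registration — classical or learned —
could recover it even in principle. The texture default (amplitude 8,
correlation length of roughly a third of the field of view) makes
displacement locally observable while keeping organ interiors uniform, so
noiseless renders still take the configured tissue means exactly.

The phantom does *not* emulate: bone, air pockets, physician contouring
variability, slice-profile effects, coil shading beyond the smooth bias
option, or Bloch-equation MR physics. Passing tests on phantoms therefore
demonstrate that the algorithms and the statistical protocol behave as
designed, not that clinical accuracy figures would be reproduced.

## Networks and training objectives

All deep strategies share one 3D U-Net (`network_spec()`, `build_network()`):
`n_levels` resolution levels, two 3x3x3 convolutions per level each followed
by instance normalization and PReLU, stride-2 convolutions for
down-sampling, transposed convolutions for up-sampling, and skip connections
by concatenation. The segmentation head is a 1-channel sigmoid; the
displacement head emits 3 channels of voxel-unit offsets, converted to
millimetres at the boundary so all external semantics are physical
(backward-warping convention). Training is plain Adam; the forward and
backward passes are implemented in the package (compiled kernels for the
convolutions, the trilinear spatial transformer and the distance
transforms), and the backward pass is verified against finite differences in
the test suite.

The displacement model minimizes

```
L_tot = lambda_ddf * (lambda_ddf_l2 * L2 + lambda_ddf_reg * L_reg)
      + lambda_seg * L_seg + lambda_img * L_img
```

with `L_reg` the bending energy (mean over voxels of the summed squared
second spatial derivatives, mixed terms doubled — zero exactly on affine
fields), `L_seg` a multi-scale soft Dice on the STL-warped planning
contours, `L_img` an L2 or normalized-cross-correlation image term, and `L2`
supervised field regression that exists only when a ground-truth DDF is
available. The reference weighting is `lambda_ddf = 1, lambda_ddf_l2 = 0,
lambda_ddf_reg = 10, lambda_seg = 100, lambda_img = 1` with L2 image
similarity and at-once (non-progressive) training — the configuration that
worked best for this task — and all weights are config-exposed.

Numerical conventions worth stating:

* Soft Dice uses `eps = 1e-5`; the multi-scale variant smooths both sides
  with Gaussian kernels (default extents 0, 2, 4 voxels) and uses the
  squared-denominator soft Dice for the smoothed comparisons, which
  coincides with the plain form on binary masks and is exactly ideal at
  self-agreement — the plain linear-denominator form would report a spurious
  residual on smoothed copies.
* The bending energy averages over voxels (not sums) so loss magnitudes
  transfer between grid sizes; it is reported per voxel with the sum taken
  over components and derivative terms, which makes `u_x = x^2` (in mm)
  evaluate exactly to 4.
* The warp samples with border (clamp) extension rather than zero padding,
  so out-of-view samples do not inject artificial dark intensities into the
  similarity terms; clamped samples get zero coordinate gradient.
* Mask propagation interpolates linearly and thresholds at 0.5; nearest
  neighbour interpolation is reserved for slice-thickness resampling.
* The progressive (coarse-to-fine) schedule trains `n_levels` stages on data
  sub-sampled by decreasing powers of two and interpolated back to the full
  grid — a frequency curriculum at constant shape, which preserves the
  network's divisibility contract at every stage; epochs split evenly with
  the remainder on the final full-resolution stage.

## The classical benchmark

`bspline_register()` implements a generic three-stage multi-resolution
free-form deformation: cubic B-spline control grids at 32/16/8-voxel
spacing, mean-squared-error similarity with light bending-energy
regularization, L-BFGS-B on the control-point offsets with the analytic
gradient obtained by chaining the warp gradient through the B-spline basis,
and warm starts between stages. The exact stage recipe of the clinical
tool it stands in for is not public; this is a standard recipe, not a
reproduction of a specific product, and its role is to be a reasonable
classical DIR comparator that shares the displacement-field semantics of
the deep pathway. The same routine supplies "realistic" ground-truth fields
for one of the displacement-model training variants.

## Evaluation protocol

`dsc()`, `hd95()` and `hd_avg()` follow the symmetric surface-distance
convention: surface voxels are foreground voxels with a face-adjacent
background neighbour; HD95 is the maximum of the two directed 95th
percentiles (linear interpolation between order statistics); HDavg is the
mean of the two directed mean distances. Distances come from an exact
anisotropic Euclidean distance transform and are validated against a
brute-force pairwise oracle. The rectum is evaluated only on slices
containing the PTV (CTV dilated by a configurable 5 mm margin) plus
15 mm — ten 1.5 mm slices — beyond each end, reflecting how rectum contours
are clinically corrected mostly near the high-dose region.

Cohort statistics deliberately weight patients, not fractions: fraction
metrics are averaged per patient first, then the cohort mean and SD are
taken over patients. Normality of the per-patient means is checked with a
Kolmogorov-Smirnov test against a normal with estimated parameters (with
the usual Lilliefors caveat on its p-values), and methods are compared with
two-sided paired t-tests at alpha = 0.05, zero-variance differences being
flagged degenerate rather than tested.

## Desk-scale study sizes

All shipped studies run on one CPU in minutes, on grids that keep the
~96 mm field of view of the clinical setup at coarser voxels:

* Unit and property tests use 8^3-20^3 grids.
* The B-spline recovery study warps a 48^3 phantom (2 mm voxels) with a
  known smooth 6 mm field and requires sub-voxel mean endpoint error.
* The deformation-recovery study (`ddfm_study_settings()`) trains the
  displacement U-Net on 50 synthetic ground-truth-field pairs on a 16^3
  grid (6 mm voxels) and evaluates on held-out fields. At this width the
  network cannot absorb population anatomy variability and deformation
  estimation at once, so the study trains on one patient's planning anatomy
  with many deformations — the patient-specialized analogue of the
  clinical-scale population training — and the vignette's claims are
  correspondingly about deformation recovery, not cross-patient transfer.
* The method-comparison study (`comparison_study_config()`) trains baseline
  models on 5 patients, fine-tunes on 3 test patients, trains the
  displacement model on true planning/fraction pairs, and evaluates all
  five methods on test fractions whose bladder volume changes by a factor
  of 1.75-2.0 with a near-rigid CTV.

Clinical-scale settings (192^3 voxels at 1.5 mm, 5-level networks, hundreds
of epochs) remain expressible through the same configuration objects but
are not exercised by the tests.

## Design choices that were genuinely open

* **DDF semantics**: fields are stored in millimetres, physical space,
  backward convention, on the fraction grid — one semantics shared by the
  classical and deep pathways, so contours propagate identically through
  either.
* **Displacement-network input**: 2-channel concatenation of (z-scored)
  planning and fraction images, the standard pairwise-registration encoding.
* **Head scaling**: the displacement head learns voxel-unit offsets and the
  mm conversion happens at the boundary, keeping the learning problem
  scale-free.
* **PTV margin**: 5 mm isotropic dilation by default, config-exposed (no
  canonical value exists for the emulated setup).
* **Learning rates**: desk-scale defaults (5e-3 baseline, 1e-3 fine-tuning,
  3e-3 displacement) are larger than typical clinical-scale settings
  because the narrow desk networks otherwise converge far too slowly;
  all are config-exposed.
* **Centroid rounding** in the crop: round-half-up per axis; out-of-grid
  windows pad with border replication.
* **Empty predictions** score DSC 0 with distances flagged missing rather
  than infinite, and are excluded from distance means with a logged count.
* **Degenerate paired tests**: all-zero differences are "not significant";
  a constant nonzero shift is reported significant but flagged degenerate.

## Known limitations

* The phantom's deformations are generated from the same smooth B-spline
  family the classical benchmark optimizes over, which flatters the
  benchmark in recovery studies; the method-comparison study avoids this by
  re-rendering fraction anatomy instead of warping it.
* Training at desk scale uses tiny networks and few patients; absolute
  metric values are not comparable to clinical reports, only orderings and
  mechanisms are. In particular, the base-4 displacement network recovers
  held-out deformations only partially (the acceptance script reports the
  achieved endpoint-error reduction): per-pair classical registration shows
  the fields are recoverable in principle, but a network this narrow, with
  piecewise-linear activations, underfits the flow-estimation mapping that
  wide GPU-scale networks learn. The bundled recovery study is therefore a
  mechanism check, not a demonstration of clinical-scale displacement
  accuracy.
* The KS normality check uses estimated parameters, so its p-values are
  conservative in the Lilliefors sense.
* No folding control or diffeomorphic parameterization: large predicted or
  optimized fields can fold, which is visible as (intended) failure in the
  volume-change scenarios.
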