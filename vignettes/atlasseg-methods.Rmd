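---
title: "Hierarchical multi-atlas segmentation: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical multi-atlas segmentation: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Organs at risk in radiotherapy planning of the trunk — liver, spleen,
kidneys, stomach — are adjacent soft-tissue structures imaged at nearly
the same Hounsfield units, so intensity alone cannot separate them.
`atlasseg` segments them hierarchically. A first stage finds bulk organ
position by warping several presegmented reference scans ("atlases") onto
the patient and fusing their transferred organ masks into a probability
map; a second stage adapts each organ estimate locally to the fine detail
of the patient scan. The first stage supplies the spatial context that
intensity lacks; the second supplies the boundary accuracy that
deformable registration lacks.

## Stage 1a: atlas-to-patient registration

Each atlas is aligned to the patient in two steps, both minimising the
negated **Mattes mutual information** (MI) between patient and atlas
intensities. MI is estimated from a sampled joint histogram with a
zero-order Parzen window on the fixed (patient) axis and a cubic B-spline
window on the moving (atlas) axis; because only statistical dependence
matters, the metric tolerates the HU-calibration and contrast differences
that defeat sum-of-squares metrics. Fixed samples whose mapped point
falls outside the atlas volume (or outside the metric mask, below) are
discarded from the histogram.

**Affine initialisation.** The transform is seeded by matching intensity
centres of mass, then optimised by a regular-step gradient descent in two
phases of 30 iterations: translations only (posture and table-position
errors dominate and rotations are limited by the flat couch), then all
twelve degrees of freedom. The linear part is parameterised as
rotations × scales × shears, with angle/log-scale/shear coordinates
scaled by the image half-extent so that one optimizer unit moves a
boundary point roughly 1 mm; this keeps the MI landscape well conditioned
enough for a first-order optimizer to recover a 10° posture change. The
metric uses 20 histogram bins and samples half of the voxels; the sample
subset is drawn once per run from the configured seed, so registrations
are exactly reproducible. Step-length control: an accepted step grows the
length by 1.2 (capped), a rejected one shrinks it by the relaxation
factor 0.5; the phase ends when the step underflows 1e-3 mm. These
optimizer internals are package choices; only the phase structure, the
iteration counts, and the bin/sampling settings are method-prescribed.

**Masked B-spline refinement.** The affine is then composed with a cubic
B-spline free-form deformation of the patient domain,
`x -> affine(x + u(x))`, with `u` interpolated from displacement vectors
on a control lattice. The lattice is refined over four stages — node
spacing 100, 73, 40, 20 mm, the geometric schedule between the
prescribed 10 cm and 2 cm endpoints — and each stage is optimised by
L-BFGS (memory 5, ≤ 60 iterations per stage, gradient tolerance 1e-5)
with an analytic MI gradient: the Parzen-window derivative per sample is
chained through the atlas image gradient and projected onto the control
nodes by the (stage-constant) sparse B-spline weight matrix of the fixed
sample points. Between stages the finer lattice is fitted so that it
reproduces the current displacement field exactly at every new node
position (a separable tridiagonal collocation solve).

Irrelevant image content — implants, catheters, couch, anatomy far from
the organs — would otherwise dominate the metric. Following the method's
masking rule, the union of the atlas organ masks is dilated by a 10 mm
margin (a true Euclidean margin in mm, isotropic on anisotropic grids)
and used as a *moving-space* gate: a fixed sample only contributes while
its currently-mapped point lies inside the dilated mask. The affine stage
is deliberately unmasked (whole-image) since it must correct gross
posture errors; this is configurable.

## Stage 1b: STAPLE fusion

The warped per-atlas masks of one organ are treated as raters of unknown
reliability, and the classic binary STAPLE EM estimates simultaneously
the voxelwise posterior probability `w` that the organ is present and
each rater's sensitivity `p` and specificity `q`. The E-step computes
`w = a / (a + b)` with `a` and `b` the foreground/background likelihoods
under the current `(p, q)`; the M-step re-estimates `(p, q)` from `w`.
Twenty iterations are run (or until the largest change in `w` falls
below 1e-6). Initialisation is `p = q = 0.9` (a common default; the
method source is silent) and the global prior is the mean rater
foreground fraction over the computation region — the bounding box of
the union of masks padded by one voxel, with `w = 0` outside. Because
the prior depends on the region, this restriction is configurable and
documented: computing over the whole volume would shrink the prior and,
with it, `w` near the boundary.

The probability map is thresholded at **0.7** (inclusive), the
empirically determined consensus level for three atlases, and the
largest 26-connected component is kept so stray crumbs cannot seed the
refinement (an artifact addition, disablable).

## Stage 2: per-structure refinement

Refinement is three chained steps; each step's output is the next one's
input.

1. **HU-interval extraction.** A histogram of the HU values inside the
   fused shape (125 equal-width bins over the in-mask range,
   right-inclusive last bin) is split into classes by multi-level Otsu
   analysis — thresholds maximising the between-class variance, computed
   by dynamic programming and verified in the tests against exhaustive
   search. The class holding the most voxels is taken to be the organ
   tissue (ties broken toward the class containing the in-mask median
   HU), and the interval is the min/max original HU among its voxels.
   The histogram mask is the seed dilated by `histogramDilationMm`
   (default 5 mm) so that neighbouring tissue forms contrast classes
   even when the fused shape hugs the organ tightly; without any
   neighbouring tissue in the mask the split lands inside the organ's
   own noise distribution and the interval collapses to a sliver — the
   degenerate case the method's description itself warns about for
   uniform regions. If the histogram has fewer distinct values than
   classes, the interval falls back to the raw in-mask range with a
   warning and a `fallback` flag.

2. **Threshold level set.** The fused shape, converted to a signed
   distance field (negative inside), is evolved for up to 500 iterations
   under `dphi/dt = -a·S·|grad phi| + b·kappa·|grad phi|` with
   propagation weight `a = 1` and curvature weight `b = 0.5`. The speed
   `S` is the piecewise-linear ramp `min(I - lower, upper - I)` clipped
   to plus/minus half the interval width and normalised by it, so the
   weights are scale-free; a hard binary speed is config-selectable.
   Propagation is discretised upwind, curvature centrally; the time step
   obeys a combined hyperbolic + parabolic CFL bound; the field is
   clamped to a narrow band of plus/minus six voxel spacings (otherwise
   the far field drifts linearly and the RMS stopping rule loses
   meaning) and reinitialised to a signed distance every 50 iterations.
   The run stops early when the RMS field change drops below 1e-5.

3. **Geodesic level set.** A short (30 iteration) geodesic
   active-contour evolution smooths the result and grows it across weak
   edges — for example an organ pole blurred by respiratory motion whose
   HU fell outside the interval: `dphi/dt = -a·g·|grad phi| +
   b·g·kappa·|grad phi| + c·grad g · grad phi` with `a = 1`, curvature
   weight `b = 3`, advection `c = 1` (the edge-attraction term of the
   geodesic formulation; set `c = 0` to disable). The edge image is
   `g = 1/(1 + |grad(G_sigma * I)|)` with `sigma = 1.5 mm`, linearly
   rescaled to [0, 1] (flattest voxel 1, strongest edge 0). A
   contrast-free image has no edges to seek: by convention the image
   force (balloon and advection) then vanishes and only the curvature
   flow acts, so the evolution is a pure shrinking regularisation rather
   than an unbounded inflation. The short iteration cap is the leak
   guard: the balloon advances only ~1 voxel into genuinely flat
   tissue in 30 iterations, while recovering several voxels of
   weak-gradient organ.

Per-organ overrides of every refinement setting are supported
(`refineOverrides`, keyed by organ label) — the method is explicitly
built around customising the filter chain per structure.

## The synthetic phantom

No clinical cohort ships with the package, so validation runs on a
synthetic generator that emulates the statistical structure of the
problem rather than anatomy: a 64³ volume at 2.5 mm isotropic voxels
(the scanner protocol emulated), a soft-tissue body at 20 HU containing
two lungs (−800 HU), a vertebral column (700 HU), a liver (60 HU),
spleen (55 HU) and two kidneys (45 HU) — several adjacent organs within
a 15 HU band, the defining difficulty — plus white Gaussian noise
(σ = 8 HU, a realistic soft-tissue noise level at this voxel size).
Atlases are the same anatomy seen through a recorded true transform: a
random smooth deformation (coarse 55 mm displacement lattice, max 8 mm —
deliberately off the registration's node schedule so recovery is not
trivially in-model) composed with a rigid posture change (±5°, ±8 mm)
and a monotone HU recalibration (slope 0.92–1.08, offset ±40). All
randomness derives from one seed; the recorded transforms let tests
measure registration error against analytic ground truth.

What the phantom does *not* model: anatomical shape realism, partial
volume effects, streak artifacts, contrast agents, and spatially
correlated noise. Passing the phantom suite therefore demonstrates the
pipeline's mechanics — transform recovery, fusion behaviour, interval
extraction, level-set dynamics — not clinical-grade accuracy.

Confounders can be injected into the patient only (`addConfounder`): a
1500 HU implant-like pellet outside the organs (the masked metric must
shrug it off), a motion-blurred kidney pole (the geodesic step must
recover it), a stomach-like blob attached to the spleen (the threshold
step must exclude it), and a missing lung (the pipeline must fail that
organ gracefully rather than crash).

`phantomSegmentationConfig()` is the standard configuration for phantom
runs. It differs from the clinical defaults only in the Otsu settings:
two classes with a one-voxel histogram shell (three classes for the
liver, which abuts lung), because the class count must match the tissue
multiplicity the histogram mask actually contains. The clinical default
of four classes reflects fused shapes that span several tissue groups;
on a two-tissue phantom a four-class split subdivides the organ's own
noise mode and yields the degenerate sliver interval discussed above.
This per-structure choice is stated once here and used unchanged by the
test suite and the acceptance script.

## Numerical choices and degenerate inputs

* Index-to-physical convention: voxel centres at
  `origin + orientation %*% (spacing * index)`, 0-based indices.
  Transforms map fixed (patient) points to moving (atlas) space — the
  resampling convention — so warped atlas masks land on the patient grid.
* Out-of-field fill: −1000 HU (air) for CT resampling, 0 for masks.
* Distance transforms are exact Euclidean (separable lower-envelope
  algorithm, compiled), in mm, anisotropy-aware; signed distances are
  negative inside.
* Masks resample nearest-neighbour and therefore stay binary; volumes
  default to trilinear interpolation.
* MI histograms clamp the moving-bin coordinate two bins from each end
  so the cubic window always fits; images with constant intensity are
  rejected.
* The B-spline metric samples are preselected once per registration
  (affine image inside the gate dilated by a further 20 mm capture
  margin) and re-gated every iteration at their currently mapped
  position; optimisation may therefore see the valid-sample count change,
  which first-order optimizers tolerate.
* STAPLE clamps `p` and `q` to [1e-6, 1 − 1e-6]; all-empty or all-full
  rater sets are errors (no evidence for one of the classes).
* An organ whose probability map never reaches the threshold raises a
  fusion-failure error; the pipeline downgrades it to a `failed` report
  entry ("needs manual segmentation") and continues with the others.
* Level-set evolutions run on a bounding box around the initial
  interface padded by 16 voxels (40 mm at default spacing) — the crop
  bounds how far a surface can travel, which is ample for the 30–500
  iteration budgets.
* Problem sizes in the shipped tests: oracle comparisons run on toy
  grids (≤ 24³); registration recovery and refinement properties on the
  standard 64³ phantom; pipeline orchestration and determinism checks on
  a 32³ phantom with proportionally reduced optimizer iterations, which
  exercises the identical code paths.

## Known limitations

* The esophagus-class failure mode of the original method — small,
  low-contrast structures contributing little to the metric — is out of
  scope; nothing in this package rescues such organs.
* Fusion uses a global scalar prior and no spatially varying model;
  rater weighting by registration quality is not implemented. With only
  three atlases, STAPLE inherits the well-known small-N weakness: when
  two raters share spatially correlated boundary errors, the EM can rate
  the correlated majority as more reliable than a solitary near-perfect
  rater, so the fused mask may sit a few Dice points below the best
  single atlas even though it is robust to outliers and beats the mean.
  The refinement stage is what recovers the remaining gap.
* The affine optimizer is first-order; pathological initialisations
  (> ~20° posture error) may need a better seed than centre-of-mass.
* Multi-label consistency is not enforced: organs are segmented
  independently and may overlap by a voxel at shared boundaries.
* DICOM networking, treatment-planning-system export and email
  notification of the original clinical deployment are replaced by a
  filesystem watcher with the same workflow shape (`watchDirectory`).
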