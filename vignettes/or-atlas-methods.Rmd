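---
title: "Methods: optic-radiation atlas construction and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optic-radiation atlas construction and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oratlas)
```

## The problem

Anterior temporal lobe surgery risks the most anterior portion of the optic
radiation, Meyer's loop. Group atlases of the tract, built from streamline
tractography in a common template space and then carried into an
individual's anatomy by inverse spatial normalization, give surgeons a
labeled volume without requiring per-patient diffusion tractography. The
scientific questions such an atlas must answer are geometric (how far
anterior does the loop reach — the tip-to-ridge distance dTM; where do the
upper and lower divisions run and how do they twist) and statistical (how
often does the individualized label actually cover the voxels where the
tract most plausibly runs — the correspondence rate).

`oratlas` implements this entire chain and, because the original diffusion
cohorts are not redistributable, validates it end-to-end on a synthetic
phantom cohort with known ground truth.

## The phantom and what it emulates

`phantom_spec()` describes a parametric bundle per hemisphere:

* it originates within 1 mm of an *LGN* point, leaves through a short stub
  (the optic-tract analogue) and turns onto the loop by a configurable
  *sharp angle* (default 80°);
* it wraps vertically around a *temporal horn* analogue — an ascending limb
  over the horn roof, a crest at a prescribed anterior ridge, and a return
  limb below the horn — before sweeping posteriorly to two cortical target
  zones (upper division ORu, lower division ORl);
* the anterior reach is parameterized by the true dTM per side:
  `ridge Y = temporal-tip Y − dTM` (defaults 23.1 mm left, 26.41 mm right,
  in the range anatomical studies report);
* *fanning* is realized by perturbing the crest and target control points
  inside a disc whose angular size at the origin is `fan_half_angle`
  (default 12°), plus a deterministic spread of per-fiber crest depths over
  a 10 mm band, so the anterior extension thins out gradually, as the real
  loop's fiber-density profile does;
* the ORu/ORl *twist* is an X-offset of opposite sign for the two divisions
  that changes sign at a fixed anterior-posterior level
  (`twist_gain`, default 1.5 mm — the divisions swap their medial/lateral
  arrangement once along the tract);
* per-point Gaussian jitter (default 0.15 mm) models digitization noise.

Fibers are *emitted by a momentum flow*: each centerline is sampled at
0.5 mm and integrated with the same direction-update rule the tracker uses
(`d ← normalize(0.8 d + 0.2 tangent)`). This makes the bundle a coherent
flow field — the rasterized mean orientation field is then (close to) a
fixed point of the tracker's own propagation rule, which is what real
tractograms are with respect to the tracker that produced them. A
per-fiber clamp guarantees the bundle envelope crests exactly at the
prescribed ridge.

A cohort (`make_cohort()`, default 30 subjects; the bundled experiments use
10 to stay fast) deforms the template through per-subject ground-truth
transforms: rotation ≤ 5° per axis, anisotropic scale within 1 ± 0.05,
translation ≤ 3 mm, plus a Gaussian-smoothed displacement field
(correlation length 20 mm, peak 2.5 mm, tapered to zero at the grid
boundary, checked diffeomorphic via the Jacobian determinant). These
amplitudes are of the order of residual anatomical variability after
template normalization.

The default grid is 2 mm isotropic — a common diffusion resolution — over
±54 × (−86, 38) × ±36 mm.

**What the phantom does not emulate:** diffusion signal, ODF
reconstruction, crossing fibers (each voxel carries a single orientation
peak), scanner artefacts, pathology, or registration *estimation* error —
transforms are generated, never estimated from images. Passing tests on the
phantom therefore demonstrate the pipeline's internal correctness and
parameter recovery, not performance on real brains.

## Tracking

`track_streamlines()` is a deterministic streamline tracker: seeds are
drawn uniformly over the seed-mask volume with uniform sub-voxel offsets;
from each seed both polarities are tracked; per step the direction field is
interpolated trilinearly with per-corner antipodal sign alignment, blended
with the previous direction (smoothing weight 0.8 on the previous
direction), and the position advanced 0.5 mm. A branch stops when
interpolated QA falls below the threshold, the per-step turn exceeds 90°,
the position leaves the grid, or the total length would exceed 300 mm;
streamlines shorter than 30 mm are discarded while still counting against
the 50,000-seed budget. The QA termination threshold has no universal
value; `suggest_qa_threshold()` provides a heuristic stand-in (smallest
threshold keeping ≥ 99 % of suprathreshold QA mass inside a tissue mask).

A known property of this update rule is a systematic outward drift on
curved tracts: over a turn of angle Θ the trajectory migrates outward by
approximately Θ·step·s/(1−s) (about 8 mm for a half-turn at step 0.5 mm,
s = 0.8), independent of the curvature radius. Real optic radiations are
wide enough to absorb this; the phantom's crest-depth band plays the same
role.

**Limitation (template recovery).** Because every fiber starts within 1 mm
of the LGN, the fan's divergence lives at sub-voxel scale near the origin;
collapsing each voxel to a single mean orientation erases it, and a
deterministic tracker can only recover the mean-field flow image of the
seed ball. Voxel-set recall of the rasterized template through the
LGN-seeded, ROI-filtered tracker therefore saturates near 55–60 % at the
2 mm default resolution (higher on coarser grids or against
density-weighted cores). The package reports this recall honestly rather
than redefining the denominator; full voxel recovery would require
multi-peak voxels or probabilistic seeding, both outside this package's
scope.

## Atlas construction and label propagation

Per-subject groups of fibers (tagged by subject, side and division) are
merged in the common space; a voxel receives a division's label when
traversed by at least `min_subject_support` distinct subjects (default 1),
overlaps resolve to the division with larger support, ties to the upper
division. TDI counts each streamline at most once per voxel, with segments
supersampled at half-voxel spacing. Rigid mask registration (centroid +
principal axes, Nelder–Mead refinement of Dice overlap) is provided for
mask-level space transfer.

Transforms are world-to-world: `p' = A p + D(A p)`. Labels are propagated
by pull-back: each target voxel center is mapped through the
(subject-to-atlas) transform and assigned the nearest source label —
nearest-neighbor only, so no new label values can appear. Inversion is
exact for the affine part and fixed-point for the field; since the inverse
of a trilinear warp is not itself trilinear, the inverse field is stored on
a refined (3×, padded) grid, which keeps round-trip errors below 0.05 mm
for the cohort's transforms. Double nearest-neighbor resampling (there and
back) restores about 98.6–99.3 % of nonzero label voxels; the residual ~1 %
is the quantization floor of nearest-neighbor label transport on a thin
tract, concentrated at region boundaries.

## Validation statistics

* **Middle-third slab**: the central third of the side's
  anterior-posterior extent, where the tract's anatomy is simplest.
* **Maximal-density voxels**: per coronal slice within the slab, all
  voxels attaining the slice maximum TDI (ties included). A global top-set
  variant is available (`per_slice = FALSE`); per-slice is the default
  because it makes CR insensitive to the absolute density profile.
* **CR**: fraction of those voxels inside the side's atlas label.
* **Shift-tolerance profile**: the labels are translated laterally in
  voxel-sized steps (emulating registration error); the *tolerable CR* is
  the CR at the largest offset at which the maximal-density voxels still
  touch the label. The full profile is reported since the single number
  depends on the offset grid.
* **Bootstrap**: percentile CI of the mean CR over 10,000 resamples; the
  reported flag (observed mean inside its own CI) is nearly always true by
  construction — the CI itself is the informative output.
* **Safety zone**: the label dilated by a Euclidean margin (default 5 mm,
  exact voxel-center distances); the check passes when all maximal-density
  voxels lie inside — the clinically relevant scenario of a modest
  mislocalization that still stays within a safe margin.
* **Sample size**: smallest n ≥ 2 such that a two-sided one-sample t-test
  (exact noncentral-t power) reaches the requested power; with a tested-CR
  mean of 75 %, a tolerable-CR mean of 4 %, SD 10 %, α = 0.05 and power
  0.90 this gives n = 3, cross-checked against a Monte-Carlo oracle in the
  tests.

On the phantom, labeling through the exact ground-truth inverse transforms
yields CR = 1 — correctly so, since the phantom has no registration
estimation error; the shift-tolerance machinery is what exercises the
imperfect-registration regime.

## Numerical and design choices

* RAS+ world mm everywhere; 0-based voxel indices with centers on integer
  indices; one unambiguous affine convention for all modules.
* dTM is an anterior-posterior (Y) difference, matching the surgical
  "distance from the temporal pole" convention; a Euclidean option exists.
* The Meyer's-loop portion is delimited by the LGN coronal plane; the
  anterior ridge is the maximal-Y vertex/voxel with ties resolved toward
  the midline.
* The twist profile treats centroid differences within 1 mm of zero as
  noise when counting sign changes (slab centroids over a few hundred
  fibers carry ~0.5–1 mm of structural and sampling noise).
* Sides are generated and measured independently; mirror symmetry with
  per-side dTM emulates left/right asymmetry.
* Streamline files use the MRtrix `.tck` dialect (world-mm float32
  coordinates — identical to the package's internal convention) with a
  JSON sidecar for tags; DICOM export is a secondary-capture-style series
  with labels burned into 12-bit pixel data and geometry tags (LPS) derived
  from the grid affine, with deterministic UIDs under a seed.

## Problem sizes used in the bundled experiments

The packaged tests and the acceptance script run 10-subject cohorts with
400 fibers per division and side on the 2 mm grid, 50,000 tracking seeds,
and 10,000 bootstrap replicates; these sizes make every experiment a
few-minute, single-CPU run while leaving all statistical machinery at its
full defaults.
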