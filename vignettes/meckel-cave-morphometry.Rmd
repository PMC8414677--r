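---
title: "Shape morphometry of the Meckel cave: methods and design"
author: "MCmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape morphometry of the Meckel cave: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MCmorph)
```

## The scientific problem

The Meckel cave (MC) is the dural recess in the middle cranial fossa
that houses the trigeminal ganglion and trigeminal cistern. In primary
trigeminal neuralgia (PTN), neurovascular contact (NVC) at the root
entry zone is the classic culprit, but a sizeable minority of patients
have no NVC, and NVC is common in asymptomatic people. One line of
evidence implicates the *shape* of the MC itself: a flatter (more
plate-like) MC on the symptomatic side, present even in patients with
no NVC on either side.

MCmorph provides the quantitative machinery for that kind of study:

1. ten 3D shape features computed from a binary segmentation mask,
2. the group/side/NVC-stratified statistical comparison battery, and
3. a synthetic bilateral cohort generator with known ground truth, so
   the whole pipeline can be validated end to end without patient
   scans.

## Shape features

A segmentation is a `VoxelMask`: a binary occupancy grid with axes
ordered (slice, row, column), physical voxel spacing in mm per axis,
and a physical origin. Coordinates are voxel-center based; the voxel at
0-based index $(i,j,k)$ sits at $\mathrm{origin} + (i,j,k)\cdot
\mathrm{spacing}$. All computations run in physical mm, so anisotropic
spacing needs no resampling.

The ten features, with their definitions:

* **Voxel volume** $V = N_v \, V_k$: occupied-voxel count times the
  volume of one voxel.
* **Surface area** $A = \sum_i \tfrac12 \lVert (b_i - a_i) \times
  (c_i - a_i)\rVert$ over the triangles $(a_i, b_i, c_i)$ of a
  triangulated isosurface of the mask.
* **Maximum 3D diameter** (Feret diameter): the largest pairwise
  Euclidean distance between surface-mesh vertices.
* **Maximum 2D diameter** in the slice (row–column, generally axial),
  column (row–slice, usually coronal) and row (column–slice, usually
  sagittal) planes: the largest pairwise vertex distance after
  dropping the orthogonal coordinate.
* **Major / minor / least axis lengths** $4\sqrt{\lambda}$ for the
  descending eigenvalues $\lambda_{major} \ge \lambda_{minor} \ge
  \lambda_{least}$ of the population covariance (divide by $N$) of
  occupied voxel-center coordinates — the axis lengths of the
  ROI-enclosing ellipsoid. A single-slice segmentation has
  $\lambda_{least} = 0$ and least axis length 0.
* **Flatness** $\sqrt{\lambda_{least} / \lambda_{major}}$, in $[0,1]$:
  1 for a sphere-like object, approaching 0 for a plate-like object or
  a single-slice segmentation.

Eigenvalue labels are assigned by sorted magnitude throughout. The
covariance convention (voxel centers, uniform weights, divide by $N$)
is the standard radiomics definition and is what makes the
single-slice case degenerate exactly to zero.

### Mesh construction

Surface area and the Feret diameters need a surface. `buildSurfaceMesh`
pads the binary grid with an empty margin (so boundary-touching ROIs
still close), smooths it with a separable Gaussian of $\sigma = 1$
voxel per axis, and extracts the 0.5 level set by marching tetrahedra
(Kuhn 6-tetrahedron cube decomposition, vertices interpolated along
grid edges and deduplicated by global edge id).

Two deliberate choices here:

* **Gaussian pre-smoothing.** Meshing the raw binary field puts every
  vertex at an edge midpoint, producing a staircase surface whose area
  systematically overestimates smooth anatomy — for a digitized sphere
  of radius 10 mm at 0.5 mm spacing the overestimate is roughly 9%.
  The smoothed 0.5 level set instead tracks the sub-voxel boundary
  position; measured against the closed forms on that same sphere the
  mesh area is within 0.1% and the Feret diameter within about 1%.
  For ROIs so small that smoothing would erase the interior (e.g. a
  single voxel), $\sigma$ falls back automatically toward the raw
  binary grid, so every non-empty mask still produces a closed mesh.
* **Marching tetrahedra rather than table-driven marching cubes.**
  The tetrahedral decomposition has no ambiguous configurations, so
  the mesh is watertight by construction — every undirected edge is
  shared by exactly two triangles — which the tests assert directly.

The Feret diameters are computed as the exact maximum over all vertex
pairs in compiled code. (The maximum is attained on the convex hull,
but no hull library is required: the exact $O(n^2)$ scan over the mesh
sizes that arise here runs in well under a second, and the test suite
checks it against an independent all-pairs oracle.)

### Accuracy on known solids

Closed forms give the expected values for discretized solids: a
sphere of radius $r$ has volume $\tfrac43\pi r^3$ and area $4\pi r^2$;
a uniform solid ellipsoid with semi-axes $(a,b,c)$ has per-axis
covariance $a^2/5$, hence axis lengths $4a/\sqrt5$ and flatness $c/a$.
At 0.5 mm spacing the sphere checks hold to well within 1–2%; at
0.25 mm the ellipsoid axis lengths are within 0.1% and flatness within
0.5%. The tests also verify that the flatness discretization error
shrinks monotonically as spacing decreases.

## The synthetic cohort generator

Real MC segmentations are not redistributable, so the generator
emulates the study design with rotated solid ellipsoid phantoms. Only
the size and flatness statistics matter downstream — the real MC is
closer to an open-ended three-fingered glove than an ellipse, but the
pipeline consumes scalar features, so a phantom family with matched
feature envelopes suffices.

Per-side geometry is parameterized by target volume and target
flatness: with $b/a$ fixed (default 0.8) and $c/a = f$, semi-axes
follow from $V = \tfrac43\pi a^3 (b/a) f$. The defaults aim at the
reported envelopes of the emulated study: volumes log-uniform in
94.23–1589.90 mm³, side flatness means 0.41 (left) and 0.39 (right),
affected-side deficit 0.02, right side affected with probability
77/115, and NVC pattern frequencies per affected side taken from the
published cross-tabulation. The $b/a = 0.8$ default reproduces the
reported minor-vs-major axis ratio and least-axis scale at those
volumes. Ages and sexes are drawn per group matching the reported
demographics, and healthy controls are recorded as NVC no/no (the
study tabulates NVC only for patients).

Per-subject flatness deviations have two components: a shared draw
(sd `betweenSubjectSd`, default 0.04) that correlates the two sides,
and an independent per-side draw (sd `withinSubjectSd`, default 0.03).
Together they give a marginal sd near the reported 0.05–0.06 while
leaving genuine within-pair variability — without the independent
component the null paired difference would be deterministic and no
type-I calibration would be possible. Within-subject volume
correlation (default 0.5) is imposed through a Gaussian copula on the
log-uniform marginals; the study reports no value for it, so it is a
parameter, not an assertion.

Reproducibility: each subject consumes its own counter-derived
substream of the master seed, so enlarging a cohort never perturbs
existing subjects, and the same seed yields byte-identical masks and
truth tables.

What the phantoms do **not** emulate: MRI intensities and partial
volume effects, segmentation-rater variability, the glove-like
concavities of the real MC, and any NVC-driven geometry (NVC status is
metadata only). Passing tests therefore demonstrate that the feature
definitions and the statistical pipeline are correct and calibrated —
not that the anatomical effect sizes of any particular study are
reproduced.

## Statistical battery

* Affected-side laterality: exact two-sided binomial test against 0.5
  (cohort sizes here make exact enumeration trivial).
* Bilateral feature comparisons: two-sided paired t-tests on
  within-subject differences (both sides come from the same subject;
  an unpaired route is available through `groupComparison` if wanted).
* Group differences: OLS of the feature on a group indicator — the
  "linear regression" formulation, numerically identical to the pooled
  two-sample t-test; a Welch flag covers unequal variances. No
  covariates by default (none are part of the emulated design).
* Sex: Pearson chi-square on the 2×2 table, continuity correction off
  by default with a Yates flag.
* Correlation screen: Kendall tau-b (tie-corrected — features tie
  after rounding) of flatness against the other nine features.
* Tables: demographics, the four-block morphology comparison
  (HC vs PTN-affected; PTN affected vs unaffected; PTN left vs right;
  HC left vs right), the NVC pattern cross-tabulation, and the
  no-bilateral-NVC subgroup rerun of the paired comparisons.

Alpha is 0.05, two-sided, with **no multiplicity correction by
default** — the emulated analysis tests ten features marginally — and
a Holm option for users who want it. Degenerate strata (fewer than 3
pairs, zero within-pair variance, constant features) are flagged in
the output rather than tested. Raw p-values are always reported;
thresholding is left to the reader.

## Calibration experiments and problem sizes

Two simulation studies validate the pipeline end to end, and their
configurations deserve a note. The affected–unaffected contrast mixes
left and right masks across subjects, so when the generator's
left/right means differ (as the defaults do), the contrast has a
nonzero expectation even with a zero affected-side deficit — the side
asymmetry, not a miscalibration. The calibration experiments therefore
equalize the side means at 0.40, which is the configuration under
which "delta = 0" is a true null:

* **Type-I error**: 500 cohorts of 30 patients at 1.0 mm spacing,
  delta = 0; the paired flatness test should reject at close to 5%.
* **Parameter recovery**: 50 cohorts of 60 patients at 0.5 mm spacing,
  delta = 0.02, per-side sd 0.01; the mean recovered deficit should be
  0.02 and detection near-certain.

Spacings were chosen as the coarsest at which flatness extraction
error stays well below the effect scale (mean absolute deviation from
truth ≈ 0.009 at 1.0 mm, ≈ 0.002 at 0.5 mm): the extraction error then
acts as a small extra noise term without biasing the contrast. These
runs use the grid-based features only (no meshing), which is what
makes 30 000+ phantom extractions cheap.

## Numerical choices and edge cases

* Isosurface level fixed at 0.5 on the (smoothed) 0/1 field; field
  values numerically equal to the level are nudged below it so
  interpolated vertices stay strictly inside grid edges and no
  degenerate triangles arise.
* Covariance eigenvalues in $[-10^{-12}, 0)$ are clamped to 0 before
  square roots; anything more negative is a hard error.
* Flatness of a zero-variance (single-voxel) mask is reported as 0 by
  `extractFeatures` (degenerate-flat), while the low-level
  `flatnessFromEigenvalues` returns `NA` with a warning for a zero
  major eigenvalue.
* Masks are accepted with any nonzero label value as "occupied"
  (exporters disagree on label conventions); rotated NIfTI orientation
  matrices are rejected with an explicit error rather than silently
  resampled, because resampling changes the features.
* Infeasible flatness draws in the generator (outside $(0.02, b/a)$)
  are redrawn up to 100 times, then error.

## Known limitations

* The feature set is the ten shape descriptors above; sphericity,
  elongation and the intensity/texture families are out of scope.
* Phantoms are ellipsoids: adequate for validating feature recovery
  and test calibration, not for morphology research on real MC shape.
* The no-NVC subgroup analysis inherits the small expected subgroup
  sizes of the emulated design (~9 per side at n = 115), so its power
  is intrinsically low; the pipeline flags rather than hides this.
* Group comparisons are unadjusted for age and sex by default.
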