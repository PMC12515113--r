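---
title: "Methods: two-stage mandible segmentation and edentulous geometry synthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage mandible segmentation and edentulous geometry synthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Virtual surgical planning of mandibular reconstruction needs the geometry of
the mandible *without* teeth: the planning target after tumor resection is an
edentulous ridge suitable for implant-borne rehabilitation, not the dentate
bone visible in the patient's CT. mandseg implements a pipeline that (i)
segments the mandible from a CT-like volume with a coarse-to-fine two-stage
3D U-Net and (ii) predicts, from the same dentate scan, anatomically valid
edentulous variants of the bone: a moderately resorbed ridge (Cawood–Howell
Class III) and a severely atrophic one (Class V). Because clinical CT
cohorts cannot be redistributed, the package ships a parametric synthetic
mandible phantom generator that makes every stage of the pipeline testable
end to end.

## Two-stage segmentation

Stage 1 sees the whole field of view resampled to a common stage resolution
(144³ voxels at scan scale) and only has to *find* the mandible. Its
predicted mask defines a world-space bounding box, padded by 5 mm on all
sides, which crops the native-resolution data for stage 2; the crop is again
resampled to the stage resolution, giving the second network a much higher
effective resolution over the bone. Four second-stage models are supported:
three single-label networks (original, Class III, Class V) and one
multi-label network whose three sigmoid output channels predict all variants
at once. The stage-1 model is always trained on the original ground truth,
so the region of interest is identical whichever second-stage variant runs
afterwards.

Because a tight crop can truncate condyles, an iterative border correction
runs after stage 2: if any predicted voxel lies within 5 voxels of the stage
grid border, a mesh is extracted from the voxel prediction (raw iso-surface,
no smoothing), its world bounds are padded by 5 mm, and the crop–predict
step repeats until the mesh bounds change by less than 2 mm on every
coordinate or 20 iterations are reached. An empty prediction at either stage
produces a structured "not detected" result rather than an error, so batch
runs fail gracefully.

The multi-label head uses independent sigmoids, not a softmax: the three
target masks are nested (Class V ⊆ Class III ⊆ original), so the channels
overlap spatially by construction and must not compete for probability mass.

## The network

No deep-learning framework is available to this package, so the 3D U-Net is
implemented directly: double (or single, see below) 3×3×3 convolution +
ReLU blocks, 2× max-pooling, nearest-neighbour upsampling with skip
concatenation, and a 1×1×1 sigmoid head. Convolutions are computed in
single-precision row sweeps in C++ (the R API stays double); exact analytic
gradients for every layer are verified against finite differences in the
test suite. The loss is soft-Dice plus binary cross-entropy per channel —
a standard choice for heavily class-imbalanced volumes — optimized with
Adam. The output bias is initialized to −2 (≈ 10 % foreground prior) so the
first epochs are not spent escaping the all-background regime.

Two configurations are shipped:

* **scan scale**: 144³ input, depth 3, 16 base channels, two convolutions
  per block — the configuration intended for real CT volumes;
* **desk scale** (`net_config_desk()`): 48³ input, depth 3, 8 base channels,
  *one* convolution per block. This trains in minutes on one CPU core and is
  the configuration used by the automated tests. The slim block halves CPU
  cost; on the synthetic phantoms it loses no measurable accuracy.

Intensity normalization clips to a (−200, 2500) HU window and rescales to
[0, 1]; the window spans air through tooth enamel.

## Training-time augmentation

The augmentation pipeline applies, each with probability 0.5 and in this
order: left–right mirroring, random rotations (−20° to 20° per axis),
isotropic scaling (0.75–1.25), translations (−30 to 30 voxels on the network
grid), and elastic deformation. Image and labels receive the identical
transform (trilinear vs. nearest-neighbour sampling); out-of-grid regions
fill with air-equivalent intensity for images and background for labels.
Intensity noise and blur are deliberately not part of the pipeline and have
no configuration switch.

Elastic "magnitude" and "sigma" conventions differ between libraries, so
this package defines its own and documents it: control points every `sigma`
voxels (drawn from 10–13), offsets uniform in ±magnitude × 0.004 voxels
(magnitude 250–1000 for stage 1, 1000–2500 for stage 2), trilinearly
upsampled to a dense displacement field. Magnitude 250 therefore means
typical displacements of about one voxel and 2500 about ten, which is the
regime the stated ranges suggest.

Augmentation is enabled by default for both stages, and for the second
stage it is not optional in practice: stage 2 is trained on tight crops
around the padded ground-truth bounding box, while at inference it receives
crops derived from the stage-1 prediction and from the iterative border
correction, whose extents differ from the training distribution. Without
the scaling and translation transforms the second-stage model overfits the
ground-truth crop scale and its accuracy collapses inside the refinement
loop (we observed held-out Dice dropping from ~0.92 to ~0.58); with them
the pipeline is robust to the box-size variation it actually meets. The
augmentation module is additionally exercised by its own invariant tests
(identity at probability 0, mirror involution, rotation cancellation,
image–label co-registration).

## The synthetic phantom

The phantom emulates the *structure* of a mandibular CT cohort, not real
anatomy: a parabolic arch centerline swept with a rounded tube cross-section
(the body), an alveolar ridge band on top of the body over the central 80 %
of the arch, posterior ascending rami with condylar and coronoid ellipsoids,
and teeth as truncated cones seated on the crest at equal arc-length
spacing. Dentition status is full, partial (a random ~60 % subset of sites,
with empty-socket notches at missing sites so the dentate image differs
non-trivially from its toothless ground truths), or edentulous. Intensities
are CT-plausible (air ≈ −1000 HU, soft tissue ≈ 60 HU, bone ≈ 1200 HU, teeth
≈ 2200 HU) with additive Gaussian noise (default sd 25 HU); a cranium-like
bone slab and a hyoid-like blob are added by default so stage-1 localization
is not vacuous.

The three ground-truth variants derive from one geometry by lowering the
ridge-band top surface: 0 mm (original), `cl3_reduction_mm` (default ~4 mm)
and `cl5_reduction_mm` (default ~8 mm), with teeth present only in the
original. This guarantees, by construction, the nesting
Class V ⊆ Class III ⊆ original and bit-identical geometry outside the
alveolar band — the properties the acceptance suite asserts. Edentulous
originals carry 80 % of the Class III reduction and no teeth, so their
Class III variant differs from the original only marginally, mirroring the
clinical observation that already-toothless mandibles need no significant
alteration.

Everything is rasterized from a continuous occupancy field that is linear
across surfaces (value 0.5 exactly on the analytic boundary). Thresholding
at 0.5 gives the binary label volumes; iso-surfacing the same field at 0.5
(`gt_mesh()`) gives sub-voxel-accurate ground-truth surfaces — the phantom
counterpart of the smooth, manually curated STL ground truths of a clinical
study. Default grid spacing is 2 mm (a ~62×54×48 volume), chosen so a full
training cohort generates in seconds; the geometry parameters are sampled
per case from ranges that keep proportions mandible-like (arch width 85–100
mm, ridge height 10–14 mm, and so on).

What the phantom does *not* model: cortical/trabecular contrast, CBCT
artifacts, metal streaks, anatomical shape variation beyond the parametric
family, and neighboring dentition of the maxilla. Passing tests therefore
demonstrate that the pipeline machinery is correct and trainable, not that
the shipped desk-scale weights transfer to clinical data.

## Mesh post-processing

Predictions are resampled back to the native grid, optionally reduced to
their largest 26-connected component, and converted to surfaces. Iso-surface
extraction uses marching tetrahedra on the Kuhn six-tetrahedra cell
decomposition — a table-free member of the marching-cubes family that is
watertight by construction; triangle orientation is fixed outward. On a
radius-10 voxel ball the enclosed volume is within 1 % of the analytic
sphere and the error decreases with resolution.

Smoothing is Taubin's two-step filter: an umbrella-Laplacian shrink step
(λ = 0.5) followed by an inflation step with a negative factor. Parameter
tables often quote both factors as positive magnitudes (λ = 0.5, ν = 0.5);
this package takes ν as the *magnitude* of the negative second step
(μ = −ν by default), with an explicit `mu` argument for the convention
where |μ| slightly exceeds λ (e.g. μ = −0.53). With 100 iterations the volume of a
voxelized sphere changes by well under 1 %, versus ≈ 20 % shrinkage for the
pure Laplacian filter at equal iteration count.

## Evaluation metrics

* **DSC** — `2|A∩B| / (|A|+|B|)`. Voxel mode counts voxels on a shared
  grid; mesh mode uses enclosed volumes, computed by voxelizing both closed
  meshes on a common fine grid (z-column ray parity) and intersecting. The
  numerator is the Boolean *intersection* — with a union it would not equal
  1 for identical inputs.
* **ASD** — symmetric average surface distance,
  `(dASD(A,B) + dASD(B,A)) / 2`, where the directed term averages over the
  vertices of one mesh the unsigned minimum distance to the *surface*
  (point-to-triangle, uniform-grid accelerated) of the other.
* **Anatomical curves** — the caudolateral curve traces the inferior (basal)
  border of the mandible and should be invariant under ridge modification;
  the dental curve traces tooth cusps, or the alveolar crest when
  edentulous, and quantifies the intended geometry change. The published
  construction is not specified algorithmically, so this package defines its
  own operationalization: meshes are assumed in the package's anatomical
  axis convention; the arch, being single-valued over the left–right axis,
  is parameterized by normalized x and divided into 100 stations; per
  station the caudolateral curve takes the centroid of near-inferior-most
  vertices (stable on the flat basal surface) over the inferior quarter of
  the height range (which keeps stations off condyle undersides), and the
  dental curve takes the superior-most vertex over the central 62 % of the
  left–right extent (which keeps stations on the alveolar band and off the
  rami). Curve distance resamples both curves to matched stations and
  averages point-to-polyline distances in both directions.

The generator exposes analytic ground-truth curves and the expected mean
dental-curve height gap between the original and Class V variants, computed
from the same geometric model with the same station convention, so the
extractor can be validated to sub-voxel accuracy (the acceptance bound is
half a voxel on the mean gap).

## Statistics

Shapiro–Wilk for normality screening, the Wilcoxon signed-rank test for
paired comparisons (zero differences discarded; all-zero difference vectors
are a flagged degenerate case), the Mann–Whitney U test for independent
groups, and the Bonferroni–Holm step-down correction for multiplicity.
Exact p-values are used for n ≤ 25 without ties, the normal approximation
otherwise. Summary tables report mean ± sd (sample sd, n−1) in the
variant-by-dental-status layout. The suite verifies calibration empirically:
type-I error within [0.03, 0.07] at nominal 0.05 over 1000 null replicates,
power ≥ 0.95 for a 1 mm shift at 0.1 mm noise, and monotonicity of Holm
between the unadjusted and Bonferroni procedures.

## Numerical and design choices

* Coordinates are voxel-center based; `world = origin + (index−1)·spacing`
  in a fixed right-handed axis order. Files are normalized to this
  convention on read; oblique NIfTI orientations are rejected explicitly.
* Resampling preserves the voxel-edge world extent; intensities are
  trilinear, labels nearest-neighbour (binarity is asserted, never assumed).
* Boxes are closed in world space; crop keeps voxels whose centers fall
  inside, clipped to the image extent, with exact origin bookkeeping.
* The stratified 70/10/20 split rounds validation and test counts per
  stratum (floor of one case each) and gives the remainder to train; the
  same assignment is reused for all ground-truth variants of a case.
* "Mesh bounds change" in the refinement loop is the maximum absolute change
  over the six bound coordinates.
* Marching-tetrahedra iso-level is 0.5 on binary masks; degenerate
  zero-area triangles are dropped at emission.
* Problem sizes in the tests — 48³ stage grids, 8 base channels, 24-phantom
  cohorts, up to 15 epochs with early stopping on validation Dice — are the
  package's desk-scale study conditions, small enough to run on a single
  CPU core while exercising every code path of the scan-scale
  configuration. Early stopping fires at validation Dice 0.90 (0.85 for the
  stage-1 localizer, which only has to place a bounding box) or after four
  epochs without improvement; the best-validation weights are kept.

## Known limitations

* The phantom family is smooth and parametric; it cannot surface failure
  modes driven by real anatomical variation or imaging artifacts.
* The curve extractor assumes canonical anatomical orientation and an arch
  that is single-valued over the left–right axis; severely rotated meshes
  must be aligned first.
* Mesh-mode Dice depends on a voxelization pitch; the default (≈ 1/150 of
  the smaller bounding box) agrees with voxel-mode Dice to < 0.01 on
  phantoms, but pathological thin structures may need a finer pitch.
* The desk-scale network is a demonstration model; clinical use would
  require the 144³ configuration, real data, and validation far beyond the
  scope of this package.
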