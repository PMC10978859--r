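---
title: "Segmentation and morphometry of filamentous structures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation and morphometry of filamentous structures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filamorph)
```

filamorph quantifies elongated biological structures — neuronal
projections, blood vessels, mitochondrial networks — in 2D microscopy
images and 3D stacks. This vignette documents the models behind each
stage, the tunable parameters and their defaults, the numerical choices
that affect reported values, and what validation on synthetic phantoms
does and does not demonstrate about real data.

## Pipeline overview

Analysis proceeds in three stages. First, a trainable random-forest
pixel classifier converts the image into per-class probability maps.
Second, thresholding a probability channel and filtering connected
components by size, shape, intensity and border contact yields a refined
binary mask. Third, the mask is quantified: particle analysis with
intensity "redirection" to the input image, skeletonization with branch
and junction accounting, width along the skeleton via local thickness,
nuclei-gated cell-body detection, and Manders overlap between two
segmented channels. A configuration-driven driver (`run_analysis()`)
orchestrates the stages over an image folder and reports a fixed
29-parameter summary per image.

## Pixel classification

Segmentation is posed as per-pixel supervised classification, the
approach popularised by trainable-segmentation tools: the user labels a
sparse set of pixels with K ≥ 2 classes, a feature vector is computed
for every pixel, and a random forest maps features to class vote
fractions. The probability map for class k is the fraction of trees
voting k, so channels sum to one at every pixel by construction.

The feature stack is controlled by `feature_config()`:

* `sigmas` — smoothing scales in pixels. Defaults: `{1, 2, 4, 8, 16}` in
  2D and `{1, 2, 4}` in 3D. Scales are in pixel units deliberately:
  classifier features describe image texture, which lives on the pixel
  grid, while all reported morphometry uses the physical calibration.
* `families` — 2D defaults are identity, Gaussian, gradient magnitude,
  Laplacian and Hessian eigenvalues; 3D defaults are identity, Gaussian,
  derivatives (gradient) magnitude, Laplacian and structure-tensor
  eigenvalues, the standard volumetric trio of derivative, Laplacian and
  structure features. Eigenvalue families contribute d planes per scale
  in d dimensions; difference of Gaussians contributes one plane per
  ordered scale pair.

All filters are separable convolutions or finite differences with
*reflect* padding. Reflect padding avoids the spurious border gradients
that zero padding would create, which would otherwise inflate false
positives along image edges. Eigenvalues of the 2D Hessian and
structure tensor use the closed form; the symmetric 3×3 case uses the
trigonometric analytic method, vectorised over voxels.

The forest defaults (`train_pixel_classifier()`) are 200 trees, per-node
feature subsampling of ⌈√F⌉ features, unlimited depth, and a fixed
training seed (17). Training and prediction are deterministic given the
same stacks, annotations and seed, which the pipeline relies on for
bit-identical reruns. Classifiers persist to a single archive holding
the forest, the feature configuration and class names; loading under a
conflicting feature configuration is an error rather than a silent
recompute, because feature mismatch would silently corrupt predictions.

One subtlety: per-pixel *vote fractions* depend on the forest's RNG
stream, and hence weakly on the order of feature planes. The class
*decision* is what the pipeline consumes, and on separable data it is
stable under feature-family reordering (tested at the 99% agreement
level). Code that needs reproducible probabilities must fix the feature
configuration, not merely the feature set.

## Mask refinement

`extract_class_mask()` thresholds one probability channel at
`prob_min`; ties (probability exactly at the threshold) are foreground.
`refine_mask()` then filters connected components. Connectivity is
8-connected in 2D and 26-connected in 3D everywhere in the package —
the same taxonomy the skeleton stage uses, so a "single object" means
the same thing at every stage.

The filters, all bounds inclusive:

* size ∈ `[size_min, size_max]`, in physical units² (2D) or units³ (3D)
  when `size_units = "physical"`, else in pixels/voxels. The config must
  say which; nothing is guessed from the calibration.
* shape ∈ `[circ_min, circ_max]`: circularity in 2D, sphericity in 3D.
  Whether a circularity-style bound is meaningful in 3D at all is
  debatable; applying it to sphericity is the natural analogue, and
  vacuous bounds `[0, 1]` disable it.
* optional per-object mean intensity in the *input* image ≥
  `intensity_min`. The wizard-style "intensity threshold" of
  interactive tools conflates two readings — a bound on the probability
  channel being thresholded, and a bound on object brightness. Both are
  exposed (`prob_min` and `intensity_min`) so either reading can be
  configured explicitly.
* `exclude_edges` removes components touching the raster border, for
  workflows that must not measure partially visible objects; it defaults
  to off so that large cells leaving the field of view are kept.

Refinement is idempotent and only removes foreground; tightening any
bound never increases the surviving object count.

## Particle morphometry

`measure_particles()` reports one record per component: pixel/voxel
count, calibrated size, boundary measure, shape, redirected intensity
statistics (mean/min/max of the input image under the object), physical
centroid and an edge flag.

2D perimeter is estimated two ways, and the choice is recorded in the
output's `boundary_method` attribute because circularity depends on it:

* `"crofton"` (default): 4-direction Cauchy–Crofton intercept estimate,
  P = (π/8)·(n_h + n_v + (n_d1 + n_d2)/√2), with transition counts taken
  along rows, columns and both diagonals (image border counts as
  background). This is the stereological estimator used by modern
  morphometry libraries; it is accurate for smooth blobs (a radius-20
  digital disk measures within 2% of 2πr) and requires isotropic
  in-plane calibration.
* `"boundary"`: Moore boundary tracing, summing calibrated steps between
  consecutive outer-contour pixel centres. This matches the classical
  particle-analyzer convention and is validated in the tests against an
  independently traced contour. Degenerate one-pixel objects have zero
  polygon length and are clamped to circularity 1.

Circularity is 4πA/P², sphericity is π^(1/3)·(6V)^(2/3)/S with S the
exposed-voxel-face surface (faces weighted by their physical area, so
anisotropic voxels are handled). Discretization can push either index
slightly above 1; values are clamped to 1 so shape bounds live on
[0, 1]. The face-count surface estimator overestimates smooth surfaces
(a digital ball's sphericity plateaus near 0.66–0.8 rather than 1);
since the same estimator is used for bounds and reports, thresholds
remain self-consistent, but sphericity values should not be compared
against mesh-based tools.

`classify_by_shape()` bins shape values into half-open intervals
[e_i, e_{i+1}), the last interval closed at 1, defaulting to the
tubular / intermediate / punctate circularity classes 0–0.33, 0.33–0.66
and 0.66–1 used for mitochondrial network morphology. A boundary value
such as 0.33 therefore lands in the upper class.

## Skeletonization and branch accounting

Masks are reduced to one-pixel-wide centerlines by sequential,
topology-preserving border peeling. Each cycle visits the face
directions in turn (4 in 2D, 6 in 3D) and deletes border pixels that
are *simple* — removable without changing local topology — and not line
endpoints, re-testing simpleness at deletion time so no parallel-thinning
artefacts arise. Simpleness uses the crossing-number characterisation in
2D (8-connected foreground / 4-connected background) and the
Malandain–Bertrand characterisation in 3D (one 26-component of
foreground in the 26-neighbourhood, one face-connected background
component in the 18-neighbourhood). The same scheme serves 2D and 3D, so
planar analysis is the 3D analysis restricted to one slice.

Any thinning erodes terminal segments by roughly the local radius —
a tube of radius r loses about r at each end, which alone would bias
centerline lengths of short tubes by up to 10%. `skeletonize_mask()`
therefore extends each endpoint along its own direction (estimated from
the last few skeleton steps) to the mask boundary with a digital ray,
restoring terminal length while staying inside the mask; with it,
straight-tube phantoms with length ≥ 20·radius recover their centerline
length within 5%. The extension can be disabled (`extend_ends = FALSE`)
when exact medial-axis semantics matter more than length fidelity.

`analyze_skeleton()` classifies pixels by skeleton-neighbour count:
endpoint (< 2), slab (= 2), junction (> 2); the three classes partition
each skeleton exactly. At thick crossings several pixels classify as
junctions; maximal adjacent clusters merge into one junction *node*, and
branch incidence is counted against nodes (nodes with three incident
branch ends are triple points, four quadruple points). Both the merged
node count and the raw junction-pixel count are reported — they answer
different questions. Branch length sums Euclidean steps between
consecutive pixel centres with per-axis calibrated deltas, so diagonal
steps in anisotropic stacks are priced correctly. Cycles yield branches
whose two ends meet the same node (or a single cyclic branch when a ring
contains no node at all); an isolated pixel is one skeleton with one
endpoint-classified pixel and no branches.

Attachment points — distinct entries of a projection skeleton into the
cell-body region — are counted as connected components of the skeleton
restricted to the dilated body mask, minus components lying entirely
inside the body. This is an implementation definition: it presumes the
projection skeleton does not pass through the body (which holds when
projections and somata are separate classes), and the halo radius
(default 2 px) absorbs small gaps between the classes.

## Local thickness and width

The width model is the largest inscribed disk/ball: at foreground pixel
p, thickness(p) is the diameter of the largest ball that fits entirely
inside the foreground and contains p,

  thickness(p) = max { 2·dt(c) : c foreground, ‖c − p‖ ≤ dt(c) },

with dt the Euclidean distance to the nearest background pixel centre
(physical units; anisotropic calibration enters both dt and the norm).
It follows that thickness(p) ≥ 2·dt(p), with equality at local maxima of
dt. The implementation computes the exact squared Euclidean distance
transform with the separable lower-envelope algorithm, then paints
spheres in decreasing-radius order; comparisons stay in the squared
domain, so on unit grids the result is exact and is tested for exact
agreement with a brute-force double-loop oracle. A mask with no
background at all has infinite thickness.

Width-along-skeleton restricts the thickness map to skeleton pixels.
Interactive pipelines implement this restriction through 32-bit image
arithmetic (background to NaN, skeleton to 0, then adding the thickness
image); filamorph implements the equivalent value-level contract
directly — `width_along_skeleton()` returns exactly
{thickness(p) : p skeleton pixel} — and `width_map()` provides the
NaN-background raster for export when the image-arithmetic artefact is
wanted. Statistics: the mean and median are taken over *all* skeleton
pixels (the median of an even count is the mean of the two middle
values); histogram bins are half-open over [width_min, width_max) with
the last bin closed, and out-of-range values are excluded from bins but
counted in `out_of_range_count` and retained in the mean/median, so the
binning choice is auditable rather than silent. Endpoint pixels are
included by default; `trim_ends = k` removes k pixels from branch ends
first for workflows that consider terminal widths artefactual.

A digitization note that matters when validating width: the inscribed
ball of a *digitized* tube depends on where the continuous centerline
sits relative to the pixel grid. A 2D band of radius r centred midway
between pixel rows digitises to 2r rows and measures exactly 2r; centred
on a pixel row it digitises to 2r + 1 rows and measures 2r + 2. In 3D
the parity effect is smaller but reversed. The phantom-based width
validations therefore place centerlines at generic (half-integer 2D,
integer 3D) grid positions and treat ±1 pixel as the attainable
accuracy of the estimator — which is also the tolerance used in the
tests.

## Cell bodies and colocalization

Thick neurites and stain accumulations mimic somata under any
shape/size filter; nuclei rarely do. `detect_cell_bodies()` therefore
keeps exactly those body-candidate components that intersect the nuclei
mask after dilating it with a Euclidean ball (default radius 5 px — the
"enlargement" makes up for nuclei being smaller than, and not always
centred in, their soma; the value is a stand-in exposed in the
configuration). Candidates are retained *whole* rather than clipped to
the intersection: downstream particle measurement needs intact objects,
and the literal intersection is available through the overlap machinery
when needed.

`manders_overlap()` computes mask-based Manders coefficients on two
segmented images: overlap = |A ∧ B| in calibrated units, M(A) =
overlap/|A|, M(B) = overlap/|B|. Both masks must be non-empty — an
empty mask makes the quotient undefined and raises an error rather than
reporting 0. Intensity-weighted Manders variants and
correlation/randomisation statistics are out of scope: the pipeline
colocalizes segmentations, not raw intensities.

## Synthetic phantoms and validation rates

`generate_phantom()` renders tubes (polyline centerline + radius),
elliptical blobs (somata, nuclei, mitochondria-like objects), a flat or
linearly graded background, and additive Gaussian noise, all seeded and
bit-reproducible. Edges are anti-aliased: a pixel's coverage fraction
blends the structure intensity into the background, exercising the
classifier with realistic soft boundaries, while ground-truth masks stay
crisp at coverage ≥ 0.5 (equivalently, centre-to-centerline distance ≤
radius). Ground truth records per-structure masks, centerline pixel
sets, arc lengths and true diameters.

`validation_rates()` turns a prediction plus ground truth into false
positive and false negative rates, both divided by the reference
measurement. For length, a skeleton pixel is *supported* when it lies
within `tolerance_px` (default 2) of a true centerline pixel, and a
centerline pixel is *recovered* when a skeleton pixel lies within the
tolerance of it; the unsupported share of measured length and the
unrecovered share of true length give the two rates. The tolerance is a
surrogate for the visual judgement used in manual validation and is
deliberately configurable — it is an artifact definition, not a claim
about perception. For counts, predicted objects without any true-mask
overlap are false positives and true structures without any predicted
pixel are false negatives.

What phantom validation shows: the geometry pipeline (segmentation →
refinement → skeleton → width) is internally consistent and recovers
known geometry under controlled degradation. What it does not show:
robustness to point-spread blur, depth-dependent attenuation,
shot-noise statistics, stain variability or touching structures —
Gaussian noise and linear background gradients are the only corruption
models, and watershed-style splitting of touching objects is explicitly
out of scope.

## The pipeline and the 29-parameter report

`run_analysis()` processes every TIFF of a folder in lexicographic
order through the selected subset of the six analysis modes (neural
projections; soma and nuclei; area, number and intensity; length and
branching; width; colocalization of segments), writing per-image CSV
tables, intermediate rasters (masks, skeleton, NaN-background width
map; probability maps in preview mode) and a structured `run.log` into
a `Results` directory beside the images. Interactive wizard-style
tuning is replaced by the preview rasters: inspect, adjust thresholds in
the config, rerun.

Every image receives the same 29-entry summary (`parameter_schema()`),
an explicit enumeration reconciling the count-style claims of
morphometry tools with their reported tables: nuclei and soma blocks
(count, total size, mean shape, mean intensity), projection block
(count, total size, mean intensity), the skeleton block (skeleton,
branch, junction, endpoint/junction/slab voxel, triple and quadruple
point counts; mean/max/sum branch length; attachment points), width
(mean, median, histogram — the vector-valued histogram is one entry),
and colocalization (M(A), M(B), colocalized size). Modes that were not
run yield explicit "not computed" markers; degenerate images (no
objects) report zero counts and undefined-marked shape/width entries.
The schema is versioned with the package: any change to it is a visible
interface change, never a silent reshuffle.

Determinism is part of the contract: identical configuration and seed
reproduce bit-identical tables, including classifier training.

## Numerical and interface choices

* Coordinates and boxes are 1-based with inclusive bounds
  (`crop_box(lo, hi)`), the R convention used across Bioconductor
  (IRanges and relatives); nested crops compose by offset addition.
  Arrays are stored `(row, column)` / `(row, column, plane)` in R's
  column-major layout.
* Probability threshold ties go to foreground; shape-class boundary
  ties go to the upper class; histogram upper-edge values go to the
  closed last bin. Every tie rule is stated where it applies.
* Masks persist as 8-bit TIFF with foreground 255 (the convention of
  interactive image-analysis tools); probability, thickness and width
  maps as IEEE-float TIFF with NaN background, readable by standard
  readers.
* Multi-channel files: channels are addressed by explicit index in the
  configuration; nothing infers channel roles from file metadata, since
  the mapping from channels to biological stains is
  acquisition-specific.
* Test problem sizes (the package's own choice of desk-scale validation
  conditions): exhaustive oracle comparisons run on rasters up to 16×16
  (2D) and 8×8×8 (3D); tube phantoms use radii 2–5 px with lengths 10–20
  times the radius; the end-to-end study condition is a 160×160 5-tube
  phantom segmented by a forest trained on 200 labels per class.

## Known limitations

* The classifier is a pixel classifier: it cannot separate touching
  objects of the same class; no watershed or instance segmentation is
  provided.
* Crofton perimeters require isotropic in-plane calibration; use the
  boundary method otherwise.
* The face-count surface estimator biases sphericity low for smooth 3D
  objects (self-consistently so).
* Endpoint extension assumes terminal segments are locally straight;
  strongly curled tips can be under- or over-extended by a few pixels.
* Holes are not filled, and hole-aware topology (genus) is not
  reported; 2D boundary tracing measures the outer contour only.
* Reading classifier archives from other tools (e.g. Weka `.model`
  files) is not supported.
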