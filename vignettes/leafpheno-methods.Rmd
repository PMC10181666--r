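---
title: "Methods: leaf phenotyping from branch-level lidar point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leaf phenotyping from branch-level lidar point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafpheno)
```

## The problem

Terrestrial lidar scans of fruit-tree canopies resolve individual leaves
well enough that leaf-level phenotypes — inclination angle, length, width,
area — can be measured without touching the tree.  `leafpheno` implements
the branch-level part of that workflow: given a branch sample whose points
carry a binary branch/leaf semantic label (from ground truth or any
external classifier — deep semantic segmentation is deliberately outside
this package), it extracts single-leaf instances and estimates the four
phenotypes per leaf, in original metric units.

The stages, each exposed as an exported function and orchestrated by
`run_pipeline()`:

1. **Preprocessing** — statistical outlier removal, voxel-grid thinning
   (default 3 mm), optional farthest point sampling to a fixed count
   (default 2048) and normalization into a 2 m cube with the inverse
   transform recorded, so measurements always happen in original meters.
2. **Single-leaf segmentation** — flat-kernel mean-shift clustering of the
   leaf-labeled points, bandwidth = the expected circumscribed-sphere
   radius of one leaf (35–55 mm for pear; 45 mm is the balanced default).
3. **Per-leaf estimation** — moving-least-squares smoothing, then:
   inclination from a total-least-squares plane fit; length and width from
   a greedy midrib walk; area from surface triangulation plus Heron's
   formula.
4. **Evaluation** — point-level precision/recall/F1/IoU per semantic
   class, mean coverage (mCov), and instance-level precision/recall at
   IoU > 0.5.

## Models and procedures

### Preprocessing

*Statistical outlier removal* discards points whose mean distance to their
`k` nearest neighbours (default `k = 16`) exceeds the global mean plus
`std_ratio` (default 1.0) standard deviations of those per-point means —
PCL-conventional defaults; the source method names the filter but not its
parameters.  The keep-rule carries a `1e-12` relative epsilon so perfectly
symmetric point sets (standard deviation numerically zero) are not
half-removed by floating-point ties.

*Voxel thinning* keeps the centroid of each occupied 3 mm voxel (centroid
rather than voxel center, to preserve surface position), with labels
decided by majority vote (semantic ties go to branch; instance ties to the
smallest id).

*Farthest point sampling* starts from a seeded random point — the start
point is the only randomness in the whole pipeline — and greedily adds the
point maximising its minimum distance to the selected set.

*Normalization* is centroid-centering with one isotropic scale chosen so
the largest axis-aligned extent equals the cube side.  Isotropy matters:
it preserves angles (inclination) and shape ratios, and makes the
recorded `(center, scale)` transform exactly invertible.

### Mean-shift instancing

The kernel is flat (uniform within the bandwidth), matching the
radius-based density reading of the method: a mode update is the centroid
of the in-radius points.  Seeds come from a grid of cell size = radius
anchored at the cloud's minimum corner — anchoring at the data rather
than the origin makes segmentation translation-equivariant; exhaustive
per-point seeding is available via `bin_seeding = FALSE`.  Modes closer
than the radius merge, higher support winning and ties falling to the
lexicographically smaller center.  Clusters smaller than `min_points`
(default 10) dissolve into their nearest surviving neighbour: occluded
leaf fragments otherwise spawn spurious instances.  There is no RNG
anywhere in this stage, so results are bit-reproducible.

### Inclination

The leaf plane is fitted by *orthogonal* (total) least squares via the
covariance eigen-decomposition, not a z-on-xy regression — steep leaves
make the regression form ill-posed.  The normal sign is fixed to a
non-negative z component, and the inclination is
`acos(|n·ẑ|) · 180/π`, folded into [0°, 90°].

### Length and width: the midrib walk

The leaf base `P` and tip `Q` are the farthest point pair (exhaustive
search; distance ties resolved by the lexicographically smallest pair, so
the result is deterministic).  The walk keeps a base point `b` (initially
`P`), examines the `k = 8` nearest not-yet-visited cloud points of `b`,
and moves to the neighbour minimising `D = ‖n − b‖ + ‖n − Q‖`; the chosen
point leaves the candidate cloud, the endpoint never does, so the walk
terminates in at most `n` steps.  Neighbours are searched in the
remaining *leaf cloud*, not in the path itself (searching the path cannot
advance).  `k = 8` is configurable; it needs to exceed the typical
surface-neighbour count at 3 mm spacing so the walk can move along the
midrib.  Equal `D` falls to the smaller point index.

**Length** is the summed consecutive distance of the walk polyline after
orthogonal projection onto `S_vein` — the plane through `P` and `Q`
perpendicular to the leaf plane.  Projection removes the walk's lateral
wobble; what remains is the midrib's arc length.

**Width** starts from `M`, the leaf point farthest from `S_vein` (a
boundary point of the widest cross section).  The *fitted midrib* is the
walk polyline projected onto `S_vein`; its nearest point to `M` defines
the terminal, and a second walk runs from `M` toward the cloud point
backing that terminal.  The measured polyline is projected onto the
cross-section plane `S` (through `M`, normal `n_leaf × n_vein`) and is
truncated, with linear interpolation, where it crosses the midrib plane:
ending on the *fitted* midrib rather than on a raw walk point removes a
systematic half-step bias (raw walk points sit up to one point spacing
off-axis, and the nearest of them to `M` is preferentially on `M`'s side).
Width is twice this projected half-path length, so asymmetric leaves
report twice their wider half — documented behaviour, inherited from the
half-width formulation.

A known, deliberate limitation: `M` is an argmax over noisy coordinates.
Smoothing removes out-of-surface noise but not the lateral component, so
`M` carries a positive selection bias of roughly the noise magnitude
(~1–2 mm at σ = 0.5 mm), which is the dominant width error for narrow
leaves.  We keep the argmax rule as published rather than substituting a
robust estimator.

### Area

The points are projected onto their principal (total-least-squares)
plane, triangulated in 2-D by a Bowyer–Watson Delaunay triangulation
(written in C++ in this package; no computational-geometry dependency is
used), and triangles are pruned when any 3-D edge exceeds `mu` times the
mean local nearest-neighbour spacing of its vertices, or when degenerate.
This projection-based construction assumes the surface is injective over
its principal plane — true for leaves, including moderately folded ones,
and for any height-field-like patch; it is *not* applicable to closed
surfaces (a full sphere has no injective projection), which the pipeline
never meshes.  The suite exercises the curved case on a 60° spherical cap
against its analytic area.

`mu = 3` is the default: on grid-like scan sampling (voxel-thinned
clouds, and the generator's stratified sampling) the nearest-neighbour
spacing equals the point spacing, and the longest legitimate Delaunay
edges are diagonal (≈1.4× spacing).  On Poisson-like random samplings the
mean nearest-neighbour distance is about half the nominal spacing, so an
equivalent bound needs `mu ≈ 4` — the cap fixture does this explicitly.

Area is the Heron sum `Σ √(p(p−a)(p−b)(p−c))` over triangles, with tiny
negative radicands from float noise clamped to zero; a cross-product
oracle asserts agreement to 1e−10 relative in the tests.

### Smoothing

MLS projects each point onto a local bivariate polynomial (order 2 by
default) fitted over the `search_radius` neighbourhood (default 12 mm,
four voxels) with Gaussian weights of bandwidth equal to the search
radius (the PCL convention).  Points with too few neighbours pass through
unsmoothed with a warning; exact planes are fixed points of the operator
to machine precision.

### Evaluation metrics

Per semantic class: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1, and
IoU `TP/(TP+FP+FN)`, plus unweighted two-class means.  (The source's
printed formulas swap FP and FN between precision and recall; the prose
definitions — the standard ones — are implemented, and a regression test
pins the orientation.)  mCov averages, over ground-truth instances, the
best IoU achieved by any predicted instance, with no one-to-one
constraint.  Instance precision/recall use greedy one-to-one matching by
descending IoU with a strict `IoU > 0.5` threshold; the tests verify
greedy matching equals exhaustive optimal matching on all small random
fixtures.  Zero-denominator ratios are reported as 0 with an explicit
`undefined` flag rather than NaN, for aggregation safety.

## The synthetic generator

`make_leaf()` builds a leaf in a local frame: a quadratic Bézier midrib
(base at the origin, tip at `(chord, 0, 0)`, a drooping mid-chord control
point), a lateral half-width profile `(width/2)·sin(π s^r)^p` — zero at
both ends, maximal at the `width_peak` arc position — or an exact
semi-elliptic profile (`profile = "ellipse"`), an optional dihedral fold
about the midrib, and a rotation/translation pose.  Sampling is
arc-length-stratified at the `leaf_spec` density (default 11 points/cm²,
mirroring a 3 mm grid) with in-cell jitter, and the silhouette boundary
(lamina edges, base, tip) is sampled explicitly — as in a real scan,
where returns come from the physical leaf margin.  Ground truth is
analytic or by quadrature: length is the Bézier arc length (adaptive
quadrature), width is exact by construction, area is a midpoint-rule
surface integral whose value moves by well under 0.1% when the grid is
doubled, and inclination is the angle between the posed normal of the
unfolded least-squares leaf plane and the zenith.

`make_branch()` attaches `n_leaves` randomly sized leaves (chord
4–11 cm, width 2–7 cm, inclination 5–85°, pear scale) to a gently bowed
cylinder (3 mm surface sampling) in a phyllotaxis-like alternating
layout, retrying until all pairwise leaf-centroid separations exceed
`min_separation`; the achieved minimum separation is reported so tests
can relate it to clustering radii.  `perturb_cloud()` adds isotropic
Gaussian jitter and removes a random spherical cap per leaf (occlusion
dropout).

The recovery benchmark uses unfolded leaves: width and area ground truth
are intrinsic (fold-invariant), and folding belongs to the
projection-contraction property tests rather than the error benchmark.
What the generator does *not* emulate: registration ghosting, beam
divergence and footprint effects, intensity, petioles as separate
structures, overlapping/touching lamina contact, and non-developable leaf
curl.  Passing the recovery suite therefore shows the estimators are
correct on clean-to-moderately-noisy leaf geometry at scan-like density;
it does not bound errors on heavily occluded or wind-deformed field scans.

## Problem sizes and runtime

The test suite and acceptance script run on one CPU in about a minute
each at these sizes, chosen to be comfortably representative: branches of
0.45–1.0 m with 6–14 leaves (3–6 × 10³ points), 50 leaves in the recovery
benchmark, 100 random meshes in the Heron oracle, and 400-point analytic
arcs for the midrib walk.

## Numerical choices, degenerate inputs

- Plane fits reject collinear/coincident inputs (relative eigenvalue
  threshold 1e−12); vertical-plane normal signs fall back to the
  largest-magnitude component.
- `build_svein()` rejects a base–tip axis parallel to the leaf normal
  (degenerate vertical leaf).
- The Delaunay code works in a rescaled unit box with an absolute
  in-circle epsilon of 1e−12; cocircular sets (regular grids) yield a
  valid, possibly non-unique triangulation — area is unaffected.
- Distance ties in the farthest pair and the walk break
  lexicographically / by smaller index: everything is deterministic for a
  fixed input.
- Leaves collapsing below 30 points, or degenerating under smoothing,
  produce a per-leaf failure record carrying the instance id;
  `phenotype_leaves()` and `run_pipeline()` continue past them.
- All randomness (FPS start, generator sampling, noise, dropout) funnels
  through explicit integer seeds; `run_pipeline()` records its seed in
  the run log.

## Known limitations

- Width inherits a positive noise bias from the farthest-point rule for
  `M` (see above) and reports twice the wider half on asymmetric leaves.
- Area is measured on the triangulated, smoothed point set: downsampled
  or hole-ridden leaves underestimate; no correction factor is applied.
- The triangulation assumes an injective projection onto the principal
  plane; folds approaching 90° or rolled-up leaves violate it.
- Whether "length" includes the petiole depends on what the instance
  contains — the farthest-pair rule measures whatever is there.
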