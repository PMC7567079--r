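---
title: "Quantifying retinal vascular architecture from fundus images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal vascular architecture from fundus images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retvasc)
```

## The measurement problem

Early diabetic retinopathy changes the *architecture* of the retinal
vasculature — the network becomes more disjointed, closed capillary
loops are lost, free-ending branches and isolated fragments accumulate —
well before the overt lesions (microaneurysms, hemorrhages, exudates)
that an ophthalmoscope picks up. Fundus photography is noninvasive and
cheap, so a pipeline that turns a fundus photograph into a small set of
interpretable architecture metrics gives a longitudinal, per-animal (or
per-patient) readout of vascular health.

`retvasc` implements that pipeline end to end:

1. **Binarize** the vessels with a Canny edge detector and morphological
   cleanup.
2. **Skeletonize** the binary mask to a one-pixel-wide centerline
   network with exactly the same connectivity and holes.
3. **Classify** every skeleton pixel by its 8-neighbourhood: an
   *extremity* (≤ 1 neighbour), a *slab* (2), or a *node* (≥ 3); cluster
   node pixels into *junctions*; trace the paths between them.
4. **Partition** the traced paths into *branches* (extremity–junction),
   *segments* (junction–junction) and *isolated elements* (components
   without a junction); resolve the loop-bearing *master* core by
   fixpoint pruning; detect *meshes* (enclosed areas) by flood fill.
5. **Emit 20 metrics** per image and compare groups with unpaired
   two-tailed Student's t-tests, backed by a noncentral-*t* power
   analysis.

All geometry is in pixel units throughout: fundus cameras differ in
field of view and no physical calibration accompanies the images, so a
micron conversion would be invented precision.

## The vessel mask: why closing is load-bearing

A Canny detector responds to intensity *edges*. A vessel is a dark
*ridge* a few pixels wide, so the detector draws **two parallel
contours**, one along each side of the vessel, wrapping around its tips.
Feeding that double contour directly to a skeletonizer would produce a
double centerline with the wrong topology everywhere.

`clean_mask()` therefore closes the edge map with a square structuring
element (`close_radius`, default 3, i.e. a 7×7 square). The two contours
of a vessel up to ~6 px wide fuse into one solid band, which then thins
to a single centerline. This choice has a hard geometric consequence:
**closing also fuses two *different* vessels whose contours are within
the closing diameter**, so the method can only distinguish vessels
whose centerlines are farther apart than roughly
`vessel width + 2*close_radius`. That resolution limit is a property of
the method, not of the implementation, and it drives two further
hygiene steps:

* `fill_sliver_px` (default 2): where a wide vessel's contours fused
  only intermittently, thin enclosed slivers of background remain and
  would read as spurious meshes. Enclosed holes whose inscribed
  (Chebyshev) radius is ≤ 2 px are filled.
* `prune_spur_px` (default 4): thinning a band-shaped mask grows short
  terminal spurs at boundary irregularities; terminal paths of ≤ 4 px
  ending at a junction are removed. Free-standing short elements are
  never pruned, so real isolated fragments survive.
* `min_mesh_px` (default 300 px²): an enclosed region smaller than this
  cannot be bounded by distinguishable vessels at the widths this
  pipeline resolves, and is dropped as a closing artifact.

### Hysteresis thresholds

The two Canny thresholds are quantiles (`canny_low_quantile` = 0.10,
`canny_high_quantile` = 0.30) of the *above-noise-floor* gradient
magnitudes, where the floor is 3× the median magnitude. Two properties
motivated this reference population. Quantiles (rather than absolute
values) make the detector exactly invariant to affine intensity
rescaling — a fundus camera's exposure and gain then cannot change the
mask. Referencing them to the noise floor (rather than to all pixels)
keeps the thresholds stable across scenes of different vessel density:
the median gradient magnitude tracks sensor noise, so the population
above 3× the median is edge-dominated whether vessels cover 4% or 8% of
the frame. With plain whole-image quantiles, a sparse scene pushes the
thresholds into the noise and a dense one pushes them above real
vessels; both failure modes were observed during development and both
vanish with the noise-floor reference.

## The skeleton graph and the element taxonomy

Skeletonization uses sequential simple-point thinning: a pixel is
deleted only when deletion provably changes neither the 8-connectivity
of the foreground nor the 4-connectivity of the background in its 3×3
neighbourhood (evaluated through a precomputed 256-entry lookup table),
and endpoint pixels are never deleted. Deletions are applied one at a
time with re-checking, so component and hole counts are conserved *by
construction* — this is the property every downstream count relies on,
and it is property-tested against an independent flood-fill oracle.

Traced edges charge 1 per orthogonal move and √2 per diagonal move
(`diagonal_step`, settable to 1 to emulate raw pixel counting). Edge
walks start from extremities and junction-adjacent slabs in fixed
(row, col) order with lexicographic neighbour preference, so the output
is bit-deterministic.

Two conventions deserve explicit statement:

* **Nodes vs junctions.** `nodes` counts node *pixels*; `junctions`
  counts 8-connected *clusters* of node pixels. A thick crossing packs
  several node pixels into one junction. These are deliberately two
  different metrics (they differ by roughly the mean cluster size).
  Note that on a rasterized cross even the four pixels diagonal-adjacent
  to the centre have ≥ 3 neighbours: node-pixel counts are a property of
  the raster, not of the abstract drawing.
* **Ring exception.** A junction-free closed ring is one *isolated
  element*. Because meshes are defined through the master structure (see
  below), such a ring bounds no mesh under the default
  `mesh_scope = "master"`; setting `mesh_scope = "all"` counts every
  bounded face of the full skeleton instead.

## Master structure and meshes

Master segments are defined mutually recursively with master junctions
(segments connected only to other master segments; junctions incident to
≥ 3 master segments). The definitions are resolved by fixpoint pruning:
start from the subgraph of segments only and repeatedly delete every
segment with an endpoint junction of degree 1. What survives is exactly
the loop-bearing core; a pure tree prunes away completely. Junctions
with fewer than three incident master segments still delimit master
segments; they just are not *master junctions*.

Meshes are the bounded faces of the rasterized master subgraph, found by
flood-filling the background 4-connectedly from the raster border. A
mesh's area is its background pixel count — vessel pixels are excluded,
a convention stated here because reproducibility demands bit-exactness.
The number of meshes equals the cycle rank (E − V + C) of the master
subgraph, which the test suite cross-checks on 100 generated rasters.

One definitional wrinkle is worth recording: the mesh index is described
in the source nomenclature as an average distance between master
junctions but *defined* as total master segment length over the number
of master segments; the formula is implemented. Likewise the prose
description of extremities ("the whole interconnected network") is
unusable as a count; the endpoint-pixel reading, consistent with the
skeleton taxonomy, is used.

Ratios with empty denominators (`mean_mesh_size` with no meshes,
`mesh_index` with no master segments, `branching_interval` with no
branches) are reported as 0 and flagged in the `zero_denominator`
attribute, keeping feature tables total.

## Statistics

Group comparison uses the pooled-variance unpaired Student's *t* with
two-tailed p-values — the pooled form, not Welch, because published
figure-caption p-values computed from mean ± SD and n reproduce under
the pooled formula (e.g. 3.44 ± 0.7265 vs 4 ± 1.936 at n = 9/9 gives
p ≈ 0.432, and 37.43 ± 3.10 (n = 7) vs 33.25 ± 3.54 (n = 8) gives
p ≈ 0.031). No multiple-testing correction is applied by default,
matching common practice for these per-feature, per-timepoint
comparisons; a Holm option exists.

Power calculations use the exact noncentral-*t* formulation: with
noncentrality δ = d·√(n₁n₂/(n₁+n₂)) and df = n₁+n₂−2, the power is the
probability that |T′| exceeds the two-sided central critical value. At
d = 1.5, α = 0.05, target power 0.8 and allocation ratio 1 this yields
n = 9 per group (18 total) with achieved power 0.8476, and n = 8 falls
short — the classic two-group design for a large standardized effect.
The test suite verifies the power value against a 200,000-replicate
Monte-Carlo rejection-rate oracle.

When several images exist per subject (both eyes, repeated frames), the
analysis unit should be the subject: average the per-image features per
subject before testing. The package exposes this as a choice rather
than hard-coding it, since the right aggregation depends on the design.

## The synthetic world: what it states and what it doesn't

`vascular_tree_spec()` defines a fundus-like scene with exact,
construction-time ground truth. Strands grow on the pixel lattice by
1-px steps under two margins:

* a **hard adjacency margin** — a new pixel may touch (8-neighbourhood)
  only the pixel it extends — which makes the raster's skeleton-graph
  topology *identical* to the recorded event counts (junctions =
  successful bifurcations, endpoints = free strand ends, loops =
  same-tree anastomoses, isolated elements = junction-free components);
* a **soft separation margin** (16 px, with exemptions for a strand's
  own tail, branch pivots, the optic-disc neighbourhood and anastomosis
  endpoints) sized so that rendering at the stated vessel widths
  (3–5 px) plus the closing reach cannot merge distinct vessels. An
  earlier 2-px margin kept the centerline truth exact but let rendering
  fuse neighbouring vessels — the scene contradicted its own ground
  truth, which showed up as 2–5× inflated junction and mesh recovery.
  The margin, the ≥ 48 px anastomosis span (so loop faces clear the
  exempt zones), and the pruning of daughters shorter than 16 px (below
  the resolving power of the stated widths) are all consequences of the
  same consistency requirement, fixed before the acceptance thresholds
  were measured and not revisited.

Defaults state the world once: a 384-px frame (a scaled-down small
animal fundus camera frame), 6 primary vessels leaving an optic-disc
circle, bifurcation probability 0.055 per step at 72° ± 12°, 4 requested
anastomoses, 12 capillary-like fragments, vessel intensity 0.30 on a
0.85 background with a 0.15 radial falloff, Gaussian noise SD 0.02.
Rendering never alters truth, so rasterization and noise effects are
*measured* by the recovery tests, not hidden.

The generator does **not** emulate: vessel crossings (real arteries and
veins cross; the margin forbids it, so junction counts on real images
will include crossing artifacts this world never shows), microaneurysms,
hemorrhages, exudates, leakage, uneven illumination beyond the radial
ramp, or motion blur. A green recovery test therefore establishes that
the pipeline recovers the architecture of *separated, clean* vasculature
within stated tolerances (junctions and meshes ±10%, total length ±15%,
aggregated over 100 scenes) — not that it is robust to pathology or
crossings.

The diabetic-like effect (`disjunction_effect()`) doubles the fragment
count and quarters the anastomosis count. On cohorts this produces the
expected signature — lower total mesh area and mean mesh size, more
isolated elements, more branches (tips that fail to anastomose stay
free) — as directions, with no magnitude claims.

## Reproducibility mechanics

Every randomized routine takes an explicit seed and restores the
caller's RNG state. Cohorts derive per-image seeds from the master seed
by a Lehmer-style integer hash modulo 2³¹−1, whose intermediates stay
below 2⁵³ and are therefore exact in doubles on every platform. Edge
traversal order, junction ids and CSV column order are all fixed, so
identical inputs give bit-identical outputs.

## Known limitations

* Junction positions recovered from rendered images are displaced a few
  pixels downstream of bifurcations (the closing fuses the crotch), and
  closely spaced junction pairs can merge; the aggregate junction count
  runs ~5–10% low on synthetic scenes.
* Total length runs ~5% low for the same reason, partially offset by
  tip rounding.
* The element taxonomy inherits the raster definition of a node; on
  abstract drawings the counts can differ from intuition (see the
  plus-sign note above).
* The Canny chain assumes dark vessels on a brighter background only in
  documentation; the detector itself is polarity-agnostic.
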