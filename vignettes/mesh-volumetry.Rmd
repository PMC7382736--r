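---
title: "Methods: mesh volumetry in meshvol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mesh volumetry in meshvol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshvol)
```

# Scope and model

`meshvol` measures the volume enclosed by a triangle surface mesh — the data
product of segmenting a hematoma (or any solid) out of CT. The package's
central question is not "what is the volume of a perfect mesh" (any correct
method answers that) but *how each estimator degrades when the mesh is
imperfect*: unclosed because a neighbouring structure clipped the
segmentation, or carrying flipped normals from a marching-cubes
reconstruction. Three estimator families are implemented and played against
each other, plus oracles that are deliberately too slow or too crude for
production use but are independent of the code paths they check.

## Projection (divergence-theorem) method

For each face with Heron area $A_f$, unit normal $u_f$ (recomputed from the
counter-clockwise winding; stored file normals are discarded), and centroid
$\bar{p}_f$, the per-axis projected volume is
$V_a = \sum_f A_f\, u_{f,a}\, \bar{p}_{f,a}$, and the estimate is
$V = k_x V_x + k_y V_y + k_z V_z$ with $\sum k_a = 1$. Because
$\int_T z \, dS = A\,\bar{z}$ holds exactly for a flat triangle, each $V_a$
equals the exact enclosed volume on a closed, consistently oriented mesh —
the weights are then irrelevant. They matter only on defective input, where
the method is undefined anyway; we default to $k = (1/3, 1/3, 1/3)$ and keep
a `normal_weighted` mode (weights proportional to the per-axis unbalanced
surface area) to illustrate how a defect-dominated direction can capture the
estimate. An open or mis-oriented mesh is *measured, not rejected*, with a
warning recorded in the estimate: quantifying that failure is the package's
purpose, so making it an error would forbid the experiment.

## Slice methods

The mesh is cut by $2^s + 1$ uniformly spaced planes perpendicular to a
chosen axis (default z, the CT axial direction). Plane–triangle
intersections give segments; segments are chained into closed polygon loops;
the enclosed area is the shoelace sum with nested loops alternating sign
(holes subtract). Two accumulation rules turn consecutive areas into
volume: the conical-frustum rule $(S_1 + S_2 + \sqrt{S_1 S_2})\,h/3$, exact
whenever cross-sections are similar (pyramids, cones), and the trapezoid
rule $(S_1 + S_2)\,h/2$, with the usual $O(h^2)$ error. For the benchmark
pyramid the composite-trapezoid error has the closed form
$(b-a)h^2 f''/12 = 20\,(20/128)^2\,4.5/12 \approx 0.1831$ at $s = 7$, which
the tests pin down.

Interpreting "segments" as $2^s$ intervals is a deliberate choice: it is
the only reading under which the trapezoid value at $s = 7$ reproduces the
reference two-decimal benchmark value (6000.18), and it links the slice and
voxel resolutions (below) through a single parameter.

## Octree voxelization

The root cell is the cube at the bounding-box minimum corner with side equal
to the largest extent — anchoring at the corner (rather than centring) makes
the axis-aligned cube benchmark exact, because cell faces then coincide with
the solid's faces. Cells whose *open* interior meets the surface
(separating-axis triangle–box test with "touching counts as separated") are
subdivided to depth $s - 1$, giving voxel unit $\mathrm{maxExtent}/2^{s-1}$;
the others become leaves classified by the parity of surface crossings along
a +x ray from the cell centre. Inside leaves contribute their full volume.

Boundary voxels are refined with the slice machinery, in two modes. The
default `slice_aligned` mode clips the global $2^s$-interval trapezoid
slices to the region not already covered by inside leaves, so the total
*equals the trapezoid slice estimate by construction* — we chose this as the
default because it makes the voxelization and trapezoid columns of any
comparison table coincide, which is the behaviour a practitioner should
expect when both use the same plane stack. The `sub_slices` mode is the
more literal per-voxel reading: each boundary cell is integrated
independently with $k$ trapezoid intervals, cross-sections clipped to the
cell footprint (Sutherland–Hodgman against the cell square). Its error at
least halves per depth increment in the tests.

## Oracles

* `signedTetVolume()`: $\sum_f \det(P_0, P_1, P_2)/6$ — exact for closed,
  consistently oriented meshes; the reference all estimators are tested
  against.
* `monteCarloVolume()`: rejection sampling in the bounding box with the
  ray-parity inside test; reports the binomial standard error
  $V_{box}\sqrt{p(1-p)/n}$ so agreement can be asserted at 3 standard
  errors.
* The analytic pyramid inequality and the ellipsoid volume
  $\tfrac{4}{3}\pi abc$ serve as closed-form oracles in the test suite.

# Synthetic phantoms

`makeBlob()` realizes a star-shaped solid: an icosphere (level $L$ gives
$20 \cdot 4^L$ faces) whose vertex in direction $d$ is placed at radius
$\rho(d)\,(1 + \sum_j s_j A\, e^{-(\theta_j/w)^2})$, where $\rho$ is the
ellipsoid radius along $d$ and $\theta_j$ the angle to the $j$-th seeded
bump direction. The three shape classes mirror how hematomas are described
clinically: *regular* (no bumps — smooth, round to ellipsoid), *irregular*
(12 small bumps of alternating sign, amplitude 0.12, width 0.35 rad —
frayed margins), *lobular* (3 positive bumps, amplitude 0.35, width 0.7 rad
— multilobular). Default semi-axes (18, 14, 13) give ≈ 13.7 ml when
coordinates are millimetres, a mid-sized bleed. Star-shapedness guarantees
a closed, self-intersection-free manifold without any repair step, and all
randomness flows through one explicit seed, so phantoms are reproducible
fixtures.

What the phantoms deliberately do **not** emulate: CT partial-volume and
thresholding noise, stair-step (marching-cubes) surface texture, sliver
triangles from real segmentations, multi-component bleeds, or non-star
topology (e.g. a hematoma wrapped around a ventricle). Passing tests
therefore demonstrate correctness of the *geometry pipeline* and the
relative robustness ordering of the estimators — not segmentation accuracy
on clinical data.

The corruptions are the two failure modes under study: `openVariant()`
removes a planar cap (benchmarks) or a small disk of faces (curved
phantoms; `runCohort()` punches a 0.15 rad disk, about 6 faces at icosphere
level 3, mirroring surfaces that arrive unclosed by a handful of facets),
and `corruptNormals()` flips a seeded fraction of windings.
`reorientMesh()` repairs the latter by breadth-first winding propagation
with the global sign chosen per connected component so enclosed volume is
positive.

# Numerical choices

* **Vertex merging** (STL is a triangle soup): grid snapping at
  $10^{-8} \times$ bounding-box diagonal. Topology analysis is meaningless
  without it.
* **Plane nudging**: a slice plane within $10^{-7} \times$ extent of any
  vertex is moved inward by that amount, so end planes and planes through
  grid vertices are well defined. This perturbs areas by $O(10^{-6})$
  relative — visible in the last printed decimals (the frustum pyramid
  value computes as 5999.99993, not 6000 exactly) and far inside every
  tolerance used.
* **Contour chaining**: endpoints match at $10^{-7} \times$ bbox diagonal;
  chains that fail to close (open meshes) are joined nearest-endpoint-first
  and counted, so a missing cap parallel to the slicing plane costs nothing
  and a small side hole costs only the chord-vs-arc sliver.
* **Triangle–box ties**: the separating-axis test treats exact touching as
  non-intersecting (and skips degenerate zero cross-axes), so a face lying
  in a cell's boundary plane marks neither neighbour as boundary — this is
  what lets the aligned cube voxelize exactly with zero boundary cells.
* **Ray-parity ties**: hits within $10^{-10}$ barycentric (or grazing in x)
  trigger a re-cast from a deterministically jittered origin (fixed jitter
  seed 0), so classification is reproducible.
* **Degenerate faces** get area 0, an `NA` normal and a flag; volume
  methods skip them and `topologyReport()` counts them, because real
  segmentation meshes contain slivers and erroring out would be useless.
* **Units** are dimensionless model units throughout; `asMilliliters()`
  divides by 1000 for meshes in millimetres, and `runCohort(units = "mm")`
  adds the clinical <10 / 10–20 / >20 ml size grouping.

# Problem sizes

The shipped tests run the benchmarks at their defining dimensions
(pyramid 30 × 30 × 20, cube edge 10) with segments up to 7 (128 slices,
voxel depth 6), blobs at icosphere levels 2–4 (320–5120 faces), Monte-Carlo
oracles at $10^5$–$2 \times 10^5$ samples, and cohorts of three phantoms
per experiment — sizes chosen so the whole suite exercises every code path
in about a minute while leaving the asymptotic claims (convergence ratios,
boundary-cell growth) measurable.

# Known limitations

* The slice and voxel estimators assume the solid is sliceable into closed
  contours; a mesh missing *side* walls entirely (not just caps or small
  holes) will be gap-closed into something else.
* `sub_slices` refinement inherits any contour-clipping error at boundary
  cells; `slice_aligned` is exact with respect to the trapezoid stack but
  reports a boundary volume that is a difference, not an independent sum.
* `reorientMesh()` requires a closed, edge-manifold mesh; it repairs
  orientation, not holes.
* Facet counts of generated meshes are controlled by subdivision parameters
  and are not meant to match any particular external triangulation; the
  estimators are demonstrably insensitive to them, which is the point.
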