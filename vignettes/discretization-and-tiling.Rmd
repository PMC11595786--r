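---
title: "Subpixel-aware discretization and on-the-fly tiling of slide annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subpixel-aware discretization and on-the-fly tiling of slide annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annotiler)
```

## The procedure

`annotiler` treats a set of class-labelled polygons in level-0 slide pixel
coordinates as the single source of truth for segmentation training data.
Five steps connect polygons to pixel masks and back:

1. **Index.** A packed Sort-Tile-Recursive (STR) R-tree is bulk-loaded over
   the annotation bounding boxes once per image (`build_index()`).
   Envelope hits are always post-filtered by an exact geometric
   intersection test: an R-tree alone over-returns, and correctness is not
   negotiable for masks.
2. **Query and clip.** A tile request (origin, size, downsample) queries
   the tree, intersects each hit with the tile rectangle, and maps the
   clipped geometry into tile-local mask coordinates
   (`get_tile_annotations()`). Zero-area boundary touches are dropped —
   a sliver of zero area can set no pixel.
3. **Rasterize.** Clipped polygons are scan-converted to a single-label
   mask or a per-class channel stack (`rasterize_annotations()`), under
   the pixel-selection rules below.
4. **Vectorize and merge.** Prediction masks come back as exact
   rectilinear polygons (`vectorize_mask()`), are rescaled and translated
   into slide coordinates (`to_slide_coords()`,
   `save_mask_annotations()`), and same-class polygons touching across
   tile borders are dissolved into single annotations
   (`merge_annotations()`).
5. **Evaluate.** Masks are scored against ground-truth polygons with
   subpixel IoU and a boundary Hausdorff distance
   (`evaluate_dataset()`).

Everything streams: `tile_pair_stream()` yields `(image tile, mask)` pairs
lazily with nothing written to disk, and two identically configured
streams are bit-identical.

## Coordinate conventions and the boundary tie rule

Coordinates are 0-based with y growing downward. Mask pixel `(r, c)` of a
tile with origin `(x, y)` and downsample `d` covers the half-open cell
`[x + c·d, x + (c+1)·d) × [y + r·d, y + (r+1)·d)`; its sampling center is
the cell midpoint. Ring orientation is normalized on read: shells to
positive shoelace sign, holes to negative (with y pointing down this is
what "counter-clockwise" means here).

Two pixel-selection strategies are implemented as pure functions of
geometry and grid:

* **center** — burn a pixel iff its cell center lies inside the polygon;
* **corner** — burn a pixel iff its top-left cell corner lies inside.

A sample point exactly on a polygon edge is decided by a half-open rule:
the point is perturbed by `(+ε, +ε)` with `ε = 1e-9` before an even-odd
ray cast, so left and top edges are inside and right and bottom edges are
outside. This single rule makes the half-pixel-offset square discretize to
exactly one 5×5 block under either strategy (different blocks, one pixel
apart), which is what produces the closed-form worked-example values
IoU = 0.6807 and HD = 0.7071. Scan conversion extracts per-row spans from
edge crossings at the sample ordinate; it is algebraically identical to
evaluating the point rule at every pixel, and the test suite checks that
equivalence against an independent per-pixel oracle by exact set equality.

The `corner` strategy is a documented baseline standing in for legacy
AWT-style polygon renderers: it agrees with `center` on integer-aligned
rectangles and is systematically worse on offset or curved shapes (its
mask equals the center-rule mask of the polygon translated by
`(+0.5, +0.5)`). It is not claimed to replicate any particular renderer
bit-for-bit; it isolates the effect of the sampling-point choice, which is
the comparison the metrics are designed to expose.

Sub-polygon slivers narrower than a pixel may burn zero pixels. No
minimum-one-pixel rule is applied — the worked-example values require the
pure point rule, and a forced pixel would silently bias area statistics.

## Metrics

**Subpixel IoU.** The mask foreground is an exact rectilinear region (a
disjoint union of pixel cells). The intersection area with the
ground-truth polygon is the sum of the polygon clipped against each
per-row run of foreground cells — Sutherland–Hodgman clipping against a
convex rectangle is area-exact even for non-convex subjects with holes, so
the IoU is the true continuous-geometry value, not a pixel-count
approximation. `IoU = 1` iff the polygon equals the polygonized mask.
Conventions: both empty → 1; exactly one empty → 0.

**Boundary Hausdorff distance.** The symmetric Hausdorff distance between
the polygon boundary (all rings) and the polygonized mask boundary, in
pixels. Each boundary is sampled at arc-length step 0.01 px plus all
vertices, and every sample's distance to the opposite boundary is computed
exactly against its segments; the reported value is therefore accurate to
about 0.005 px, far below the 4-decimal comparisons it feeds. Because the
distance-to-boundary function is 1-Lipschitz along the boundary, a coarse
pre-pass (step 0.5 px) discards stretches whose upper bound cannot reach
the running maximum; this prunes most of the work without changing the
sampled result. Conventions: both boundaries empty → 0; exactly one
empty → `Inf`, reported as such and excluded from dataset means.

**Dataset evaluation.** Each annotation is rasterized in its own
bounding-box-aligned region padded by 2 px — the region choice is
otherwise free, and a per-shape box keeps grids small without touching the
metrics. Summaries (`glance()`) report mean and *population* standard
deviation (n divisor); the std flavor is a documented convention, and
directional comparisons in the tests use means only.

## Vectorization and merging

For every label, each 4-connected component becomes one polygon whose
boundary follows pixel-cell edges exactly; enclosed background becomes
interior rings. 4-connectivity is deliberate: 8-connected components can
corner-touch, which has no valid representation as a simple polygon.
Boundary tracing emits directed unit edges with the interior on the left
and chains them; at pinch vertices (shell and hole meeting at a point) the
sharpest right turn is taken, which separates the pinch into simple
loops. Staircase vertices are kept — no simplification — so that
`rasterize(vectorize(M)) == M` holds bit-exactly, a property the suite
checks on random multi-label masks.

Merging computes the transitive closure of "same class AND geometric
distance ≤ `distance`" (default 0 = touching; the radius is exposed
because "nearby" is otherwise underspecified) and replaces each group by
its union. Transitive closure rather than pairwise iteration is a
deliberate choice: it makes the result independent of input order, at the
price that a chain of annotations merges as one. The union is computed
exactly for rectilinear inputs on the coordinate-compressed grid of all
vertex ordinates — a compressed cell is covered iff its midpoint is inside
any member, which is exact because member edges lie on compressed grid
lines. Mask-derived annotations are rectilinear by construction, which is
the intended input; a group with non-rectilinear members raises an error
rather than returning an approximate union. Members that touch only at a
corner stay one annotation with a multipolygon geometry. Untouched
annotations keep their original order; merged unions follow.

## The synthetic data

`generate_star_polygons()` emulates an artificial annotation benchmark: 55
polygons of 24 vertices around a fixed center, with mean vertex radius
increasing linearly from 3 px to 60 px so the set spans sub-pixel detail
up to many-pixel shapes. Vertex angles are evenly spaced plus a uniform
perturbation of up to `jitter·π/n` and a random rotation; vertex radii are
uniform in `±30%` of the schedule radius, rescaled so each polygon's mean
radius sits exactly on the schedule (the dataset's size progression is
then monotone by construction, not by luck). With `jitter = 0` each
polygon is exactly a regular n-gon, giving a closed-form area the tests
check. Sorted-angle construction guarantees simple, valid polygons;
vertices are rounded to 1e-6 px so regeneration is bit-identical across
platforms for a fixed seed. The radius range, vertex count and jitter are
fixed defaults chosen to span the sub-pixel-to-smooth regime; dataset-mean
metrics depend on them, so only the *direction* of the center-vs-corner
comparison is asserted, never exact means.

`make_toy_shapes()` builds the four worked-example shapes: the
integer-aligned square `[1,4]²`, the half-pixel-offset side-5 square
`[0.5,5.5]²`, and a disk with and without a half-pixel center offset
(radius 3 by default, polygonized as a 256-gon — disk radius and segment
count are configurable because the reference values for curved shapes
depend on them, and only the squares have parameter-free closed forms).

`make_synthetic_image()` paints each class at a fixed intensity into its
own channel over a flat background, with optional seeded Gaussian noise.
It emulates just enough of a multi-channel fluorescence tile for
end-to-end tests — constant-intensity regions with sharp polygon
boundaries. It does not model staining physics, texture, vignetting,
focus, or pyramid resolution levels, so passing end-to-end tests
demonstrate the correctness of the geometry pipeline, not segmentation
performance on real tissue.

## Numerical choices

* Boundary ties: `ε = 1e-9` perturbation, applied identically in the
  point test and the scan conversion.
* Zero-area filtering of clipped slivers at `1e-12`; merge touch
  tolerance and coordinate snapping at `1e-9` (tile borders from integer
  grids agree exactly; the tolerance absorbs downsample arithmetic).
* GeoJSON coordinates are written at full double precision; round trips
  are vertexwise identical.
* Invalid input geometries (self-intersecting rings, zero-area rings,
  holes outside shells) are rejected with the offending feature named,
  not silently repaired — a repair step would change areas behind the
  user's back. Simplicity checking is O(n²) per ring and skipped above
  512 vertices.
* Single-label overlap tie-break: input order, later annotations
  overwrite earlier ones (drawing-order convention); deterministic by
  contract. Channel mode preserves overlaps instead.
* Downsampled image reads use block means over the cell's source pixels —
  deterministic and well-defined for non-integer factors (pixels are
  assigned to cells by their centers).
* Tile grids ceil-cover the image; overhanging tiles are zero-padded.

## Problem sizes in the test suite

The suite generates everything in code: oracle-equivalence sweeps use 100
random star polygons on grids up to 64², roundtrip checks 100 random
multi-label masks up to 64², Monte-Carlo IoU validation uses 10⁶ points
per pair on 20 pairs (3-standard-error agreement), and the dataset-level
directional checks use the full 55-star set plus disks of radius 2–8.
These sizes keep a full run around a minute on one core while leaving the
statistical checks well-powered.

## Known limitations

* Flat raster images only (PNG/TIFF arrays); pyramidal WSI containers
  (SVS, NDPI) and live QuPath project files are out of scope — GeoJSON is
  the exchange format.
* `merge_annotations()` unions only rectilinear geometries (its intended
  mask-derived input); free-form polygon unions are not provided.
* The corner baseline is a model of legacy renderers, not a bit-exact
  replica; conclusions about specific external tools should be drawn from
  the direction of the comparison, not 4th-decimal values on curved
  shapes.
* Hausdorff values are sampled (±0.005 px), not closed-form; exact
  segment-pair optimization was deliberately traded for simplicity with a
  stated error bound.
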