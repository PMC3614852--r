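---
title: "Reconstructing 3D surfaces from serial-section image stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing 3D surfaces from serial-section image stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicemesh)
```

## The problem

Serial cryosectioning, block-face photography, and related protocols
produce an ordered stack of 2D cross-sectional images of an opaque
specimen: fine in-plane resolution (a fraction of a millimetre per pixel)
but much coarser sampling between slices (often a millimetre or more).
Turning such a stack into a triangulated surface that can be rendered,
measured, or fed to downstream simulation requires four steps, executed in
a fixed order: slice preparation, slice-to-slice registration,
segmentation, and isosurface reconstruction. `slicemesh` implements this
pipeline with an emphasis on testability: every stage can be exercised on
synthetic phantoms with analytically known geometry, so the whole chain is
verified end to end without any external data.

## Registration model

Each photographed slice may be shifted, rotated, or slightly scaled
relative to its neighbours (camera drift between exposures). Because the
sections are physically parallel, the misalignment is modelled as a 2D
affine transform per slice, written as a 3×3 matrix acting on homogeneous
pixel coordinates $(x, y, 1)$. Protocols embed alignment rods in the
specimen block; each slice then shows a small set of bright marker disks.
Three non-collinear markers determine the six affine parameters exactly —
which is precisely why classic protocols used three rods — and more
markers are handled by least squares with a reported residual.

The marker detector is deliberately simple and documented as a stand-in
for whatever feature detector a production system would use: threshold to
an intensity window, 8-connected components, discard components smaller
than 4 px, keep the expected number of largest components, and take
intensity-weighted centroids with the weight measured above the window
floor. Weighting above the floor matters: pixels near the threshold then
contribute almost nothing, so the centroid varies smoothly as the marker
moves by sub-pixel amounts instead of jumping when rim pixels enter or
leave the window. Correspondence across slices is by sorted (y, x) label
order, not nearest-neighbour matching — valid because inter-slice jitter
is small compared with marker separation, and degenerate exactly when two
markers share a y coordinate to within the jitter, which the phantom
default layout avoids. Slices are resampled into the reference frame with
bilinear interpolation (monotone, no overshoot at mask edges; bicubic
would ring).

## Volume assembly and inter-slice interpolation

Registered (and optionally masked) slices stack into a voxel-centred
scalar volume $D(x_i, y_j, z_k)$ with spacings $(\Delta x, \Delta y,
\Delta z)$. Isosurfacing wants a grid homogeneous in every direction, so
the volume is interpolated to $\Delta z' = \Delta x$ before
reconstruction. Two interpolants are provided:

* **linear** — new z-samples are convex combinations of the two bracketing
  slices. Exact for fields linear in z, bound-preserving, and the right
  choice for grayscale data.
* **shape** (default for masks) — each binary slice is replaced by its
  signed Euclidean distance transform (negative inside), the distance
  fields are interpolated linearly in z, and the result is re-thresholded
  at zero. Interpolated cross-sections are then geometrically plausible
  intermediate shapes rather than translucent blends; a disk growing
  between two slices stays a disk. This is classic shape-based
  interpolation; the distance transform comes from `EBImage::distmap()`.

Sample positions at original slice planes are copied, never interpolated,
so isotropization conserves the measured data exactly where it exists.

## The marching-cubes kernel

The kernel walks every cell of 8 neighbouring samples. Corner $i$ of a
cell carries state $S_i = 1$ when its value $q_i \ge C_0$ (the isovalue)
and 0 otherwise; a corner exactly at the isovalue counts as inside, with
no epsilon nudging. The states pack into an 8-bit index, $\sum_i S_i 2^i$,
with the corner numbering chosen so that the bits of $i$ literally spell
the corner's (x, y, z) offsets — a convention that is self-documenting and
directly testable. Of the 256 configurations, 255 place at least one
corner inside, and under the 24 proper rotations of the cube combined with
global state complementation the 256 configurations fall into exactly 15
equivalence classes; both counts are recomputed by brute force in the test
suite and the acceptance script rather than assumed.

The case table is generated, not hand-enumerated: the 15 class
representatives carry the classic base-case tessellations (transcribed
into this package's numbering), every configuration reachable by rotation
inherits a rotated copy, and the remainder take their complement's entry
with reversed winding — same intersected edges, opposite orientation.
Construction is self-checking: an unassigned index, a non-empty entry at 0
or 255, or an entry whose edges disagree with the sign-change edges of its
configuration aborts with an error, since any of these indicates a broken
base case.

Iso-points are placed on sign-change edges by linear interpolation,

$$ Q = \frac{C_0 - q_i}{q_j - q_i}, \qquad
   \mathbf{p} = \mathbf{P}_i + Q\,(\mathbf{P}_j - \mathbf{P}_i). $$

One published formulation of the interpolation weight divides by
$q_j - C_0$ instead; that form is not a valid interpolant (it divides by
zero when the far corner sits at the isovalue and has the wrong endpoint
limits), so the standard quotient above is used and the discrepancy is
flagged here deliberately.

Vertex normals come from central differences of the density,

$$ g_x = \frac{D_{i+1,j,k} - D_{i-1,j,k}}{\Delta x}, $$

written without the conventional factor 2 in the denominator — the scale
cancels in normalization, so the convention is kept exactly as commonly
printed. At boundary samples a one-sided difference substitutes (logged).
Gradients at the two edge endpoints are blended with the same $Q$ as the
position, normalized, and negated so normals run from high values to low —
outward for a bright-inside volume. Where the gradient vanishes (constant
neighbourhood) the mean geometric normal of the incident triangles is the
fallback.

### Numerical choices

* **Welding** is by exact grid-edge identity, not coordinate hashing:
  adjacent cells reference the same vertex object with no tolerance
  parameter to tune.
* **Ties** ($q_i = C_0$) follow the ≥ rule exactly. An exact hit puts the
  iso-point on a corner; triangles whose iso-points coincide have zero
  area and are dropped (counted and logged). Because welding is by edge
  identity, two coincident iso-points on *different* edges remain distinct
  vertices, so a mesh containing exact hits can report boundary edges in
  the index-level census even where it is geometrically closed. Generic
  data never hits this; the phantoms place their centres at odd quarters
  of a millimetre so that no grid sample lands exactly on the surface.
* **Boundary clipping**: if the isosurface crosses the outermost sample
  layer the mesh is clipped there and a warning recommends `pad = TRUE`,
  which wraps the volume in a below-isovalue layer (origin shifted by one
  spacing) so the surface closes.
* **Ambiguous faces**: a cell face with one diagonal inside and the other
  outside admits two tessellations. The classic 256-entry table — and any
  table built from it by rotation and complementation, including this
  one — does not resolve every such face consistently between neighbouring
  cells, so adversarial data (e.g. iid noise contoured mid-range) can
  produce meshes with cracks. On smooth data at reasonable resolution,
  including all phantoms in the test suite, the meshes are watertight;
  watertightness is always *checked*, never assumed, before a volume is
  computed. Topologically guaranteed variants (asymptotic decider,
  trilinear-topology tables) are out of scope.

## Mesh metrics and export

Watertightness is an edge-incidence census (closed ⇔ every undirected edge
borders exactly two triangles); the Euler characteristic $V - E + F$
separates sphere topology (2) from torus topology (0) and is additive over
components. Enclosed volume is the divergence-theorem sum of signed
tetrahedra against the origin, with the absolute value taken at the end —
translation invariance is a test, not a property of the raw formula — and
surface area is the plain triangle-area sum. Meshes export to binary STL
(80-byte header, little-endian count, 50-byte records), OBJ, and ASCII
PLY; all writers are deterministic (fixed header text, no timestamps) so
identical meshes give byte-identical files, which is what makes the
pipeline's end-to-end determinism testable.

## The phantom generator

Phantoms are analytic solids — sphere, torus, and a tube swept along a
cubic-spline centerline — sampled as signed-distance fields (negative
inside) and rendered as 8-bit slice stacks. Design choices worth knowing:

* Inside is negative in fields and bright in renders; the default
  isovalues are 0 and 127.5 respectively, fixing the ≥ convention
  unambiguously.
* Rendered slices put the solid interior at 200 with a one-pixel
  antialiasing ramp (so its half level is 100), and fiducial markers
  brighter still: a cone from 255 at the centre to 228 at the rim with a
  2 px skirt back to background. Keeping the whole marker disk inside the
  detection window [228, 255] makes the floor-weighted centroid a smooth
  moment of a tent-shaped weight, accurate to a few hundredths of a pixel
  even after bilinear warping — the property the registration accuracy
  tests rely on.
* Noise is Gaussian, seeded, and added after rasterization (or after
  field sampling), never to the geometry, so stored ground truth —
  per-slice marker positions and jitter transforms — stays exact.
* The tube's distance field is computed against 1000 dense centerline
  samples; this is approximate (exact only in the limit) but far below
  voxel resolution for any phantom in the suite.
* Default stack geometry (0.33 mm pixels, 1 mm slice spacing) mirrors a
  typical cryosection photographic protocol; the test phantoms use 1–2 mm
  spacings and 32³-scale grids so the full suite runs in seconds. The
  acceptance checks use the r = 10 mm sphere at 1 mm isotropic spacing on
  a 32³ grid, the oracle comparison uses one hundred 8³ volumes, and the
  resolution-convergence check uses 0.5/1/2 mm spacings.

What the phantoms do **not** emulate: tissue texture, colour anatomy,
partial-volume mixing of multiple materials, staining variation, or
segmentation ambiguity. Passing tests therefore demonstrate the geometry
and numerics of the pipeline, not the adequacy of simple thresholding as a
segmentation method for real anatomy — the package treats segmentation as
an input (mask files) with thresholding as plumbing for self-contained
runs.

## Known limitations

* Classic-table topology: cracks are possible on data with inconsistently
  resolved ambiguous faces (see above).
* JPEG ingestion is not supported (no JPEG codec among the package's
  dependencies); masks that passed through lossy compression are still
  handled faithfully by the ≥128 binarization rule once converted to
  PNG/TIFF.
* Colour is reduced to luminance at ingestion; colour-aware segmentation
  is out of scope.
* In-plane anisotropy (Δx ≠ Δy) is rejected rather than resampled.
* Registration is strictly 2D affine per slice from labelled landmarks:
  no intensity-based, non-rigid, or volumetric registration.

## A worked example

```{r example, eval = FALSE}
spec <- phantom_spec("sphere",
                     list(center = c(15.75, 15.75, 15.75), radius = 10),
                     grid_shape = c(32, 32, 32), spacing = c(1, 1, 1))
vol  <- generate_field(spec)
mesh <- extract_isosurface(vol, isovalue = 0)
watertight_check(mesh)$is_closed
euler_characteristic(mesh)
enclosed_volume(mesh)     # compare against (4/3) * pi * 10^3
surface_area(mesh)        # compare against 4 * pi * 10^2
write_mesh(mesh, "sphere.stl")
```

The same computation runs end to end, from rendered slices through
masking and isotropization, with `run_pipeline()`; see the README for the
printed output.
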