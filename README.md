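# slicemesh

Surface reconstruction of serial-section image stacks by marching cubes.

Serial cryosectioning and block-face photography produce ordered stacks of
2D cross-sectional images: sub-millimetre pixels in-plane, millimetre-scale
gaps between slices, per-slice misalignment from camera drift, and
segmentation delivered as binary masks. `slicemesh` turns such a stack
into a measurable triangle mesh through a fixed four-stage pipeline —
preparation → registration → segmentation/masking → volume assembly →
isosurface reconstruction — and validates every stage against synthetic
phantoms with analytically known geometry. It is aimed at researchers who
need a transparent, fully tested reference implementation of this
workflow rather than a black-box rendering tool.

## The method

**Registration.** Slice misalignment is a 2D affine transform
$T$ (a 3×3 matrix on homogeneous pixel coordinates) per slice, estimated
from matched fiducial markers — the bright disks left by alignment rods
embedded in the specimen block. Three non-collinear markers determine the
six parameters exactly; more are fit by least squares. Each slice is then
resampled into the reference slice's frame by inverse-mapped bilinear
interpolation.

**Volume and interpolation.** Registered, masked slices stack into a
scalar volume $D(x_i, y_j, z_k)$, interpolated in z to isotropic spacing.
Grayscale volumes interpolate intensities linearly; binary mask volumes
interpolate the per-slice signed Euclidean distance transform and
re-threshold at zero, so inserted cross-sections are geometrically
plausible shapes.

**Marching cubes.** Each cell of 8 neighbouring samples gets an 8-bit
index from the corner states $S_i = [q_i \ge C_0]$. A 256-entry case
table — generated from 15 base cases by the 24 proper rotations of the
cube plus complementation with reversed winding, and verified at build
time — maps the index to triangles whose vertices are placed on the
intersected edges by linear interpolation,
$Q = (C_0 - q_i)/(q_j - q_i)$. Per-vertex normals are central differences
of $D$ blended along the edge, oriented from high values to low. Meshes
are checked for watertightness (every edge borders exactly two
triangles), measured (Euler characteristic, divergence-theorem volume,
surface area), and written as binary STL, OBJ, or ASCII PLY.

**Phantoms.** Spheres, tori, and spline-swept tubes with optional
fiducial disks, per-slice affine jitter, and seeded Gaussian noise
provide ground truth for every stage; identical spec + seed reproduces
output bit for bit.

## A worked example

```r
library(slicemesh)

spec <- phantom_spec("sphere",
                     list(center = c(15.75, 15.75, 15.75), radius = 10),
                     grid_shape = c(32, 32, 32), spacing = c(1, 1, 1))
vol  <- generate_field(spec)      # signed distance, negative inside
mesh <- extract_isosurface(vol, isovalue = 0)
mesh
#> <iso_mesh> 1896 vertices, 3788 triangles, with normals
watertight_check(mesh)$is_closed
#> [1] TRUE
euler_characteristic(mesh)
#> [1] 2
enclosed_volume(mesh)             # analytic: (4/3) pi 10^3 = 4188.79
#> [1] 4163.924
surface_area(mesh)                # analytic: 4 pi 10^2 = 1256.64
#> [1] 1252.693
```

The reconstructed ball of radius 10 mm sampled at 1 mm is watertight with
sphere topology; its volume is 0.6% and its area 0.3% below the analytic
values — the expected small bias of a piecewise-linear surface inscribed
in a smooth one. The same reconstruction runs end to end from rendered
slices, including masking and isotropization from 2 mm slice spacing:

```r
r <- run_pipeline(list(
  phantom   = phantom_spec("sphere", list(center = c(23.5, 23.5, 15), radius = 10),
                           c(48, 48, 16), c(1, 1, 2)),
  mask      = list(threshold = c(100, 230)),
  isotropic = TRUE, interp = "shape",
  output    = "sphere.stl", seed = 1))
r$metrics$enclosed_volume_mm3
#> [1] 4264.022
```

A thin command-line wrapper lives at `inst/cli/slicemesh.R`:

```sh
Rscript inst/cli/slicemesh.R phantom --shape sphere --out stack/ --grid 32,32,32 --radius 10
Rscript inst/cli/slicemesh.R reconstruct --in stack/ --threshold 100,230 --isotropic --interp shape --output sphere.stl
Rscript inst/cli/slicemesh.R metrics sphere.stl
```

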