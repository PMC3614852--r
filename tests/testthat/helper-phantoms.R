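# Shared phantom fixtures. All fixtures are generated in code at test time;
# sizes are kept small enough that the whole suite runs in a few minutes.

# the reference sphere study: r = 10 mm sampled at 1 mm isotropic spacing.
# The centre sits at an odd multiple of 1/4 mm so that, at the spacings
# used in the tests (0.5/1/2 mm), no sample lands exactly on the surface
# (an exact hit is legal but collapses the local triangles to dropped
# slivers, which would cloud the metrics; see the methods vignette).
sphere_spec <- function(noise = 0, seed = 1, spacing = 1) {
  n <- as.integer(round(30 / spacing)) + 2L
  ctr <- rep(floor((n - 1) * spacing / 2) + 0.75, 3)
  phantom_spec("sphere", list(center = ctr, radius = 10),
               rep(n, 3), rep(spacing, 3), noise_sigma = noise, seed = seed)
}

torus_spec <- function(seed = 1) {
  phantom_spec("torus",
               list(center = c(15.5, 15.5, 15.5), major_radius = 9,
                    minor_radius = 3.5),
               c(32L, 32L, 32L), c(1, 1, 1), seed = seed)
}

tube_spec <- function(seed = 1) {
  phantom_spec("tube",
               list(control_points = rbind(c(10, 14, 8), c(16, 18, 16),
                                           c(22, 14, 24)),
                    radius = 4),
               c(32L, 32L, 32L), c(1, 1, 1), seed = seed)
}

# three well-separated alignment markers in general position (distinct y)
markers3 <- function() {
  list(list(center = c(8, 8), radius = 4),
       list(center = c(39, 14), radius = 4),
       list(center = c(11, 39), radius = 4))
}

# anisotropic marked stack: 48 x 48 px at 1 mm, 16 slices at 2 mm
marked_stack_spec <- function(noise = 0, jitter = NULL, seed = 3) {
  phantom_spec("sphere", list(center = c(23.5, 23.5, 15), radius = 10),
               c(48L, 48L, 16L), c(1, 1, 2), noise_sigma = noise,
               fiducials = markers3(), jitter = jitter, seed = seed)
}

# octahedron with vertices at distance 1 on the axes
octahedron_mesh <- function(center = c(0, 0, 0)) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  v <- sweep(v, 2, center, `+`)
  tr <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
              c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  iso_mesh(v, tr)
}

# axis-aligned unit cube as 12 triangles with outward winding
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  tr <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0 face (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  iso_mesh(v, tr)
}

quiet_extract <- function(...) {
  suppressWarnings(suppressMessages(extract_isosurface(...)))
}
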