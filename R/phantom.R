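#' Specify a synthetic anatomical phantom
#'
#' Phantoms are analytic solids — sphere, torus (axis along z), or a tube
#' swept along a spline centerline — sampled into signed-distance volumes
#' and rendered slice stacks with known ground truth, so every pipeline
#' stage can be tested without external data. Distances are negative
#' inside the solid. Optional per-slice affine jitter emulates camera
#' drift between photographs, bright fiducial disks emulate alignment
#' rods, and additive Gaussian noise emulates sensor noise. Noise is added
#' after rasterization, never to the geometry, so the recorded ground
#' truth stays exact.
#'
#' @param shape `"sphere"`, `"torus"`, or `"tube"`.
#' @param shape_params list of real parameters in mm:
#'   sphere `center` (3-vector), `radius`; torus `center`, `major_radius`,
#'   `minor_radius` (minor < major); tube `control_points` (k x 3 matrix of
#'   centerline control points), `radius`.
#' @param grid_shape integer 3-vector of sample counts, each >= 4.
#' @param spacing positive 3-vector of sample spacings, mm.
#' @param noise_sigma additive Gaussian noise sd (intensity units; >= 0).
#' @param fiducials optional list of disks replicated on every slice, each
#'   `list(center = c(x, y), radius = r)` in mm (slice coordinates).
#' @param jitter optional per-slice perturbation: either a list of
#'   [affine2d()] (one per slice) or
#'   `list(translation = t_px, rotation = r_deg)` maxima for seeded uniform
#'   draws; the first slice is never jittered.
#' @param seed integer; identical spec + seed gives bit-identical output.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("sphere", "torus", "tube"),
                         shape_params, grid_shape, spacing,
                         noise_sigma = 0, fiducials = NULL, jitter = NULL,
                         seed = 1L) {
  shape <- match.arg(shape)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 4))
    stopf("phantom_spec: grid_shape components must be >= 4")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stopf("phantom_spec: spacing must be three positive reals (mm)")
  if (noise_sigma < 0) stopf("phantom_spec: noise_sigma must be >= 0")
  p <- shape_params
  switch(shape,
    sphere = {
      if (is.null(p$center) || is.null(p$radius) || p$radius <= 0)
        stopf("phantom_spec: sphere needs center and radius > 0")
    },
    torus = {
      if (is.null(p$center) || is.null(p$major_radius) || is.null(p$minor_radius))
        stopf("phantom_spec: torus needs center, major_radius, minor_radius")
      if (p$minor_radius <= 0 || p$major_radius <= p$minor_radius)
        stopf("phantom_spec: torus needs 0 < minor_radius < major_radius")
    },
    tube = {
      if (is.null(p$control_points) || is.null(p$radius) || p$radius <= 0)
        stopf("phantom_spec: tube needs control_points and radius > 0")
      p$control_points <- matrix(as.numeric(p$control_points), ncol = 3)
      if (nrow(p$control_points) < 2)
        stopf("phantom_spec: tube needs >= 2 control points")
    })
  if (!is.null(fiducials)) {
    for (f in fiducials)
      if (is.null(f$center) || is.null(f$radius) || f$radius <= 0)
        stopf("phantom_spec: each fiducial needs center (x, y) and radius > 0")
  }
  structure(list(shape = shape, shape_params = p, grid_shape = grid_shape,
                 spacing = spacing, noise_sigma = noise_sigma,
                 fiducials = fiducials, jitter = jitter,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# dense centerline samples for the tube phantom (cubic natural spline
# through the control points; 1000 samples — adequate for a phantom,
# documented as approximate)
tube_centerline <- function(cp, n = 1000L) {
  tpar <- seq(0, 1, length.out = nrow(cp))
  tout <- seq(0, 1, length.out = n)
  cbind(stats::spline(tpar, cp[, 1], xout = tout, method = "natural")$y,
        stats::spline(tpar, cp[, 2], xout = tout, method = "natural")$y,
        stats::spline(tpar, cp[, 3], xout = tout, method = "natural")$y)
}

# signed distance of the spec'd solid at points (n x 3 matrix, mm)
phantom_distance <- function(spec, pts) {
  p <- spec$shape_params
  switch(spec$shape,
    sphere = sqrt(rowSums(sweep(pts, 2, as.numeric(p$center))^2)) - p$radius,
    torus = {
      q <- sweep(pts, 2, as.numeric(p$center))
      sqrt((sqrt(q[, 1]^2 + q[, 2]^2) - p$major_radius)^2 + q[, 3]^2) -
        p$minor_radius
    },
    tube = {
      cl <- tube_centerline(p$control_points)
      d2 <- rep(Inf, nrow(pts))
      for (s in seq_len(nrow(cl))) {
        d2 <- pmin(d2, (pts[, 1] - cl[s, 1])^2 + (pts[, 2] - cl[s, 2])^2 +
                     (pts[, 3] - cl[s, 3])^2)
      }
      sqrt(d2) - p$radius
    })
}

phantom_extent_check <- function(spec) {
  p <- spec$shape_params
  lo <- hi <- NULL
  switch(spec$shape,
    sphere = {
      lo <- as.numeric(p$center) - p$radius
      hi <- as.numeric(p$center) + p$radius
    },
    torus = {
      r <- c(p$major_radius + p$minor_radius, p$major_radius + p$minor_radius,
             p$minor_radius)
      lo <- as.numeric(p$center) - r
      hi <- as.numeric(p$center) + r
    },
    tube = {
      cl <- tube_centerline(p$control_points)
      lo <- apply(cl, 2, min) - p$radius
      hi <- apply(cl, 2, max) + p$radius
    })
  gmax <- (spec$grid_shape - 1) * spec$spacing
  for (d in 1:3) {
    if (lo[d] < 0 || hi[d] > gmax[d])
      stopf("phantom: solid extent [%g, %g] mm exceeds the grid along %s (0..%g mm)",
            lo[d], hi[d], c("x", "y", "z")[d], gmax[d])
  }
  invisible(TRUE)
}

#' Sample a phantom's signed-distance field
#'
#' Evaluates the solid's signed distance (negative inside) at every voxel
#' centre and adds seeded Gaussian noise of sd `noise_sigma`. The analytic
#' ground truth is attached as attribute `"truth"`.
#'
#' @param spec a [phantom_spec()].
#' @return a [volume3d()].
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  phantom_extent_check(spec)
  g <- spec$grid_shape; sp <- spec$spacing
  xs <- (seq_len(g[1]) - 1) * sp[1]
  ys <- (seq_len(g[2]) - 1) * sp[2]
  zs <- (seq_len(g[3]) - 1) * sp[3]
  pts <- cbind(rep(xs, times = g[2] * g[3]),
               rep(rep(ys, each = g[1]), times = g[3]),
               rep(zs, each = g[1] * g[2]))
  d <- phantom_distance(spec, pts)
  if (spec$noise_sigma > 0) {
    d <- d + with_seed(spec$seed, stats::rnorm(length(d), sd = spec$noise_sigma))
  }
  vol <- volume3d(array(d, dim = g), spacing = sp)
  attr(vol, "truth") <- list(shape = spec$shape, shape_params = spec$shape_params)
  vol
}

# render one z-level: solid interior at 200, fiducial disks at 255,
# background 0, with a one-pixel linear ramp at every boundary (an
# antialiased edge keeps pixel-count areas and weighted centroids accurate
# to a fraction of a pixel)
render_slice <- function(spec, z) {
  g <- spec$grid_shape; px <- spec$spacing[1]
  w <- g[1]; h <- g[2]
  xs <- rep((seq_len(w) - 1) * px, each = h)
  ys <- rep((seq_len(h) - 1) * spec$spacing[2], times = w)
  pts <- cbind(xs, ys, z)
  d <- phantom_distance(spec, pts)
  solid <- matrix(200 * clamp01(0.5 - d / px), h, w)
  fid <- matrix(0, h, w)
  # marker profile: cone from 255 at the centre to 228 at the rim, then a
  # continuous skirt down to 0 over 2 px. Keeping the full disk inside the
  # detection window [228, 255] makes the window-floor-weighted centroid a
  # smooth moment of a tent function, accurate to a few hundredths of a
  # pixel even after bilinear resampling.
  skirt <- 2 * px
  for (f in spec$fiducials %||% list()) {
    dist <- sqrt((xs - f$center[1])^2 + (ys - f$center[2])^2)
    fim <- matrix(ifelse(dist <= f$radius,
                         228 + 27 * (f$radius - dist) / f$radius,
                         228 * clamp01(1 - (dist - f$radius) / skirt)), h, w)
    if (any(fim > 0 & solid > 0))
      stopf("phantom: fiducial disk at (%g, %g) mm overlaps the solid's silhouette at z = %g mm",
            f$center[1], f$center[2], z)
    fid <- pmax(fid, fim)
  }
  pmax(solid, fid)
}

phantom_jitter_transforms <- function(spec) {
  nz <- spec$grid_shape[3]
  j <- spec$jitter
  if (is.null(j)) return(replicate(nz, affine_identity(), simplify = FALSE))
  if (is.list(j) && length(j) && inherits(j[[1]], "affine2d")) {
    if (length(j) != nz)
      stopf("phantom: need one jitter transform per slice (%d != %d)",
            length(j), nz)
    return(j)
  }
  tmax <- j$translation %||% 0
  rmax <- j$rotation %||% 0
  w <- spec$grid_shape[1]; h <- spec$grid_shape[2]
  ctr <- c((w + 1) / 2, (h + 1) / 2)
  with_seed(spec$seed + 1L, {
    lapply(seq_len(nz), function(k) {
      if (k == 1) return(affine_identity())
      A <- affine_translation(stats::runif(1, -tmax, tmax),
                              stats::runif(1, -tmax, tmax))
      if (rmax > 0)
        A <- affine_compose(A, affine_rotation(stats::runif(1, -rmax, rmax), ctr))
      A
    })
  })
}

#' Render a phantom as a slice stack with ground truth
#'
#' Renders each z-level of the phantom to an 8-bit grayscale image (solid
#' interior bright at 200, background 0), stamps the fiducial disks
#' (brighter still, 255), applies the per-slice jitter transform, and adds
#' seeded noise. Ground truth — the stamped per-slice fiducial centres (in
#' px, after jitter) and the jitter transforms themselves — is attached as
#' attributes `"fiducial_truth"` and `"jitter_truth"`.
#'
#' @param spec a [phantom_spec()] with equal x and y spacing.
#' @return a [slice_stack()].
#' @export
generate_slice_stack <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  phantom_extent_check(spec)
  sp <- spec$spacing
  if (abs(sp[1] - sp[2]) > 1e-12)
    stopf("phantom: slice rendering needs equal x and y spacing")
  px <- sp[1]
  nz <- spec$grid_shape[3]
  jt <- phantom_jitter_transforms(spec)
  base_centers <- NULL
  if (!is.null(spec$fiducials)) {
    base_centers <- t(vapply(spec$fiducials,
                             function(f) as.numeric(f$center) / px + 1,
                             numeric(2)))          # mm -> 1-based px
  }
  imgs <- vector("list", nz)
  truth_fid <- vector("list", nz)
  for (k in seq_len(nz)) {
    img <- render_slice(spec, (k - 1) * sp[3])
    A <- jt[[k]]
    if (any(unclass(A) != diag(3))) img <- resample_slice(img, A)
    imgs[[k]] <- img
    if (!is.null(base_centers)) truth_fid[[k]] <- affine_apply(A, base_centers)
  }
  if (spec$noise_sigma > 0) {
    imgs <- with_seed(spec$seed, lapply(imgs, function(m) {
      m[] <- pmin(255, pmax(0, m + stats::rnorm(length(m), sd = spec$noise_sigma)))
      m
    }))
  }
  imgs <- lapply(imgs, function(m) round(m))       # 8-bit quantisation
  st <- slice_stack(imgs, pixel_size = px, slice_spacing = sp[3])
  attr(st, "jitter_truth") <- jt
  if (!is.null(base_centers)) attr(st, "fiducial_truth") <- truth_fid
  attr(st, "seed") <- spec$seed
  attr(st, "shape") <- spec$shape
  st
}
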