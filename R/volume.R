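#' Voxel-centred scalar volumes
#'
#' A `volume3d` stores a 3D scalar grid `D[i, j, k]` with grid spacings
#' (dx, dy, dz) in mm and an origin: the physical position of sample
#' `(1, 1, 1)` is `origin`, and sample `(i, j, k)` sits at
#' `origin + ((i-1) dx, (j-1) dy, (k-1) dz)`. The first array index runs
#' along x (image columns), the second along y (rows), the third along z
#' (slice order). Every dimension must be at least 4 so that central
#' differences have interior samples.
#'
#' @param data numeric 3D array.
#' @param spacing positive 3-vector (dx, dy, dz), mm.
#' @param origin numeric 3-vector, mm.
#' @return object of class `volume3d`.
#' @export
volume3d <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3)
    stopf("volume3d: 'data' must be a 3D array")
  if (any(dim(data) < 4))
    stopf("volume3d: every dimension must be >= 4 (got %s)",
          paste(dim(data), collapse = "x"))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("volume3d: spacing must be three positive reals (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3 || any(!is.finite(origin)))
    stopf("volume3d: origin must be a finite 3-vector")
  structure(list(data = unname(data * 1.0), spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s samples, spacing (%g, %g, %g) mm, origin (%g, %g, %g)\n",
              paste(dim(x$data), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' Assemble a slice stack into a scalar volume
#'
#' Stacks registered slices into a `volume3d`: `D[i, j, k]` is the
#' luminance of pixel (row j, column i) in slice k where the mask is 1 and
#' 0 elsewhere. In-plane spacing is the pixel size; z spacing is the slice
#' spacing; the origin is (0, 0, 0). Masks replace the manual segmentation
#' step of a hand-traced workflow: supply them from files or from
#' [threshold_mask()].
#'
#' @param stack a [slice_stack()].
#' @param masks optional [slice_stack()] of 0/1 images with matching
#'   dimensions.
#' @return a [volume3d()].
#' @export
stack_to_volume <- function(stack, masks = NULL) {
  stopifnot(inherits(stack, "slice_stack"))
  d <- dim(stack$images[[1]])
  nz <- length(stack$images)
  if (!is.null(masks)) {
    stopifnot(inherits(masks, "slice_stack"))
    if (!identical(dim(masks$images[[1]]), d) || length(masks$images) != nz)
      stopf("stack_to_volume: mask stack dimensions do not match the image stack")
  }
  vol <- array(0, dim = c(d[2], d[1], nz))   # x = columns, y = rows
  for (k in seq_len(nz)) {
    img <- stack$images[[k]]
    if (!is.null(masks)) img <- img * (masks$images[[k]] != 0)
    vol[, , k] <- t(img)
  }
  volume3d(vol, spacing = c(stack$pixel_size, stack$pixel_size,
                            stack$slice_spacing))
}

#' Build a mask stack by intensity windowing
#'
#' A simple automatic stand-in for manual segmentation: mask = 1 where
#' `low <= value <= high` (both bounds inclusive).
#'
#' @param stack a [slice_stack()].
#' @param low,high window bounds on the \[0, 255\] intensity scale.
#' @return a [slice_stack()] of 0/1 images.
#' @export
threshold_mask <- function(stack, low, high) {
  stopifnot(inherits(stack, "slice_stack"))
  if (low > high) stopf("threshold_mask: low (%g) > high (%g)", low, high)
  masks <- lapply(stack$images, function(m) (m >= low & m <= high) * 1.0)
  slice_stack(masks, pixel_size = stack$pixel_size,
              slice_spacing = stack$slice_spacing, names = stack$names)
}

#' Interpolate a volume to isotropic spacing
#'
#' Serial-section data is almost always coarser between slices than within
#' them; isosurfacing wants a grid that is homogeneous in each dimension.
#' New z samples are placed at multiples of the in-plane spacing and
#' filled by interpolation between the two bracketing original slices;
#' original slice planes that coincide with a new sample are copied
#' exactly, and the output depth is `round((depth - 1) * dz / dz') + 1`.
#'
#' Two interpolants are provided. `"linear"` interpolates intensities —
#' appropriate for grayscale data. `"shape"` is for binary (mask-derived)
#' volumes: each slice is converted to its signed Euclidean distance
#' transform (negative inside), the distance fields are interpolated
#' linearly in z, and the result is re-thresholded at 0, so interpolated
#' cross-sections stay geometrically plausible instead of fading through
#' intermediate gray levels.
#'
#' @param vol a [volume3d()] with equal x and y spacing and `dz >= dx`.
#' @param method `"linear"` or `"shape"`.
#' @return a [volume3d()] with spacing `(dx, dx, dx)`.
#' @export
interpolate_to_isotropic <- function(vol, method = c("linear", "shape")) {
  stopifnot(inherits(vol, "volume3d"))
  method <- match.arg(method)
  sp <- vol$spacing
  if (abs(sp[1] - sp[2]) > 1e-12)
    stopf("interpolate_to_isotropic: in-plane spacing is anisotropic (dx=%g, dy=%g); resample in-plane first", sp[1], sp[2])
  dz <- sp[3]
  newdz <- sp[1]
  if (dz < newdz - 1e-12)
    stopf("interpolate_to_isotropic: dz (%g) is finer than dx (%g); only z-refinement is supported", dz, newdz)
  if (abs(dz - newdz) < 1e-12) return(vol)
  d <- dim(vol$data)
  depth2 <- as.integer(round((d[3] - 1) * dz / newdz)) + 1L
  tt <- (seq_len(depth2) - 1) * newdz / dz       # in units of original slices
  tt <- pmin(tt, d[3] - 1)
  k0 <- pmin(floor(tt), d[3] - 2)
  f <- tt - k0
  f[abs(f) < 1e-9] <- 0
  f[abs(f - 1) < 1e-9] <- 1
  src <- vol$data
  if (method == "shape") {
    if (!all(src %in% c(0, 1)))
      stopf("interpolate_to_isotropic: method 'shape' needs a binary volume")
    src <- array(0, dim = d)
    for (k in seq_len(d[3])) {
      m <- vol$data[, , k]
      src[, , k] <- EBImage::distmap(1 - m) - EBImage::distmap(m)
    }
  }
  out <- array(0, dim = c(d[1], d[2], depth2))
  for (m in seq_len(depth2)) {
    a <- src[, , k0[m] + 1]
    out[, , m] <- if (f[m] == 0) a
      else if (f[m] == 1) src[, , k0[m] + 2]
      else (1 - f[m]) * a + f[m] * src[, , k0[m] + 2]
  }
  if (method == "shape") out <- (out <= 0) * 1.0
  volume3d(out, spacing = c(sp[1], sp[2], newdz), origin = vol$origin)
}
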