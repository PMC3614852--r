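#' Ordered stacks of 2D cross-sectional images
#'
#' A `slice_stack` holds an ordered list of equally-sized grayscale slices
#' (matrices of float intensities in \[0, 255\], rows = y, columns = x),
#' together with the in-plane pixel size and the inter-slice distance, both
#' in millimetres. List order is ascending z. The defaults mirror a typical
#' cryosection photographic protocol: 0.33 mm pixels at 1 mm slice
#' intervals.
#'
#' @param images list of numeric matrices with identical dimensions.
#' @param pixel_size in-plane pixel edge length, mm (> 0).
#' @param slice_spacing distance between adjacent slices, mm (> 0).
#' @param names optional character vector of per-slice source identifiers.
#' @return object of class `slice_stack`.
#' @export
slice_stack <- function(images, pixel_size = 0.33, slice_spacing = 1.0,
                        names = NULL) {
  if (!is.list(images) || length(images) == 0)
    stopf("slice_stack: 'images' must be a non-empty list of matrices")
  dims <- vapply(images, function(m) dim(as.matrix(m)), integer(2))
  bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
  if (length(bad))
    stopf("slice_stack: slices %s differ in dimension from slice 1",
          paste(bad, collapse = ", "))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stopf("slice_stack: pixel_size must be a positive scalar (mm)")
  if (!is.numeric(slice_spacing) || length(slice_spacing) != 1 || slice_spacing <= 0)
    stopf("slice_stack: slice_spacing must be a positive scalar (mm)")
  names <- names %||% sprintf("slice_%04d", seq_along(images) - 1L)
  structure(list(images = lapply(images, function(m) unname(as.matrix(m) * 1.0)),
                 pixel_size = pixel_size, slice_spacing = slice_spacing,
                 names = as.character(names)),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<slice_stack> %d slices of %d x %d px, pixel %g mm, spacing %g mm\n",
              length(x$images), d[1], d[2], x$pixel_size, x$slice_spacing))
  invisible(x)
}

#' @export
length.slice_stack <- function(x) length(x$images)

# read one image file as a float [0,255] grayscale matrix.
# RGB is collapsed with the ITU-R 601 luma weights 0.299/0.587/0.114.
read_image_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = stopf("read_stack: JPEG input is not supported (no JPEG codec available); convert '%s' to PNG or TIFF", basename(path)),
    stopf("read_stack: unsupported image format '.%s' (%s)", ext, basename(path))
  )
  if (length(dim(a)) == 3) {
    if (dim(a)[3] >= 3) {
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a <- a[, , 1]
    }
  }
  unname(a * 255)
}

read_sidecar <- function(dir) {
  sc <- file.path(dir, "stack.json")
  if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else NULL
}

#' Read a slice stack from image files
#'
#' Reads a directory (or an explicit file list) of PNG/TIFF slices into a
#' [slice_stack()]. Files are ordered by natural filename order, so
#' `slice_2` precedes `slice_10`. RGB images are converted to luminance
#' (0.299 R + 0.587 G + 0.114 B); values are floats in \[0, 255\]. A
#' `stack.json` sidecar written by [write_stack()] supplies the spacing
#' metadata; explicit arguments override it.
#'
#' @param path directory containing image files, or a character vector of
#'   image file paths.
#' @param pixel_size,slice_spacing spacing metadata in mm; override the
#'   sidecar when given.
#' @return a [slice_stack()].
#' @export
read_stack <- function(path, pixel_size = NULL, slice_spacing = NULL) {
  if (length(path) == 1 && dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                        ignore.case = TRUE, full.names = TRUE)
    side <- read_sidecar(path)
  } else {
    files <- as.character(path)
    side <- NULL
  }
  if (length(files) < 2)
    stopf("read_stack: need at least 2 slices, found %d", length(files))
  files <- files[natural_order(basename(files))]
  imgs <- lapply(files, read_image_gray)
  dims <- vapply(imgs, dim, integer(2))
  bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
  if (length(bad))
    stopf("read_stack: slice dimensions differ from the first slice: %s",
          paste(basename(files)[bad], collapse = ", "))
  slice_stack(imgs,
              pixel_size = pixel_size %||% side$pixel_size %||% 0.33,
              slice_spacing = slice_spacing %||% side$slice_spacing %||% 1.0,
              names = basename(files))
}

#' Write a slice stack as numbered PNG files plus a JSON sidecar
#'
#' Slices are written as `slice_0000.png`, `slice_0001.png`, ... (8-bit
#' grayscale, values clamped to \[0, 255\]) and the spacing metadata — plus
#' any phantom ground truth attached to the stack — goes into `stack.json`.
#'
#' @param stack a [slice_stack()].
#' @param dir output directory (created if missing).
#' @return invisibly, the sidecar path.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "slice_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(stack$images)) {
    png::writePNG(clamp01(stack$images[[k]] / 255),
                  file.path(dir, sprintf("slice_%04d.png", k - 1L)))
  }
  side <- list(pixel_size = stack$pixel_size,
               slice_spacing = stack$slice_spacing,
               n_slices = length(stack$images))
  for (a in c("fiducial_truth", "seed", "shape")) {
    v <- attr(stack, a)
    if (!is.null(v)) side[[a]] <- v
  }
  jt <- attr(stack, "jitter_truth")
  if (!is.null(jt))
    side$jitter_truth <- lapply(jt, function(A) as.vector(t(unclass(A))))
  sc <- file.path(dir, "stack.json")
  jsonlite::write_json(side, sc, auto_unbox = TRUE, digits = NA)
  invisible(sc)
}

#' Read and write binary mask stacks
#'
#' Masks are single-channel images binarised on ingestion with the 8-bit
#' rule: values >= 128 become 1, everything else 0. That rule keeps masks
#' faithful even when they went through a lossy codec that introduced
#' ringing around edges. Masks written by this package are clean 0/255 PNG
#' files, for which the rule is exact.
#'
#' @param path directory or file list of mask images.
#' @param companion optional [slice_stack()]; mask dimensions must match it.
#' @return a [slice_stack()] whose images take values in {0, 1}.
#' @export
read_mask_stack <- function(path, companion = NULL) {
  st <- read_stack(path,
                   pixel_size = if (!is.null(companion)) companion$pixel_size else NULL,
                   slice_spacing = if (!is.null(companion)) companion$slice_spacing else NULL)
  st$images <- lapply(st$images, function(m) (m >= 128) * 1.0)
  if (!is.null(companion)) {
    d0 <- dim(companion$images[[1]])
    d1 <- dim(st$images[[1]])
    if (!identical(d0, d1))
      stopf("read_mask_stack: mask dimensions %dx%d do not match companion stack %dx%d",
            d1[1], d1[2], d0[1], d0[2])
    if (length(st$images) != length(companion$images))
      stopf("read_mask_stack: %d masks for %d slices",
            length(st$images), length(companion$images))
  }
  st
}

#' @rdname read_mask_stack
#' @param masks a [slice_stack()] of 0/1 images.
#' @param dir output directory.
#' @export
write_mask_stack <- function(masks, dir) {
  stopifnot(inherits(masks, "slice_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(masks$images)) {
    png::writePNG((masks$images[[k]] != 0) * 1.0,
                  file.path(dir, sprintf("mask_%04d.png", k - 1L)))
  }
  invisible(dir)
}
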