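#' Detect fiducial markers on a slice
#'
#' Serial-section protocols embed alignment rods in the block; each slice
#' then shows a small set of bright marker disks from which the per-slice
#' transform can be recovered. Detection is deliberately simple: threshold
#' the slice to an intensity window, take 8-connected components, discard
#' specks smaller than 4 px, and return the `expected_count` largest
#' components' intensity-weighted centroids (weighted by intensity above
#' the window floor). Labels are assigned by
#' ascending (y, x) centroid order, which matches markers across slices as
#' long as inter-slice jitter is small compared to marker separation.
#'
#' @param image numeric matrix (rows = y, columns = x), \[0, 255\] scale.
#' @param expected_count number of markers to find (>= 3).
#' @param intensity_window length-2 vector; pixels with
#'   `low <= value <= high` are candidate marker pixels.
#' @return a `fiducial_set`: list with `points` (n x 2 matrix of (x, y)
#'   centroids in px) and `labels`.
#' @export
detect_fiducials <- function(image, expected_count = 3,
                             intensity_window = c(228, 255)) {
  if (expected_count < 3)
    stopf("detect_fiducials: expected_count must be >= 3")
  img <- as.matrix(image)
  h <- nrow(img); w <- ncol(img)
  inw <- img >= intensity_window[1] & img <= intensity_window[2]
  ids <- which(inw)
  if (length(ids) == 0)
    stopf("detect_fiducials: found 0 of %d markers", expected_count)
  rr <- ((ids - 1) %% h) + 1L
  cc <- ((ids - 1) %/% h) + 1L
  # 8-connectivity: link each candidate pixel to its E, S, SE, SW neighbours
  edges <- NULL
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    r2 <- rr + d[1]; c2 <- cc + d[2]
    ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= w
    ok[ok] <- inw[cbind(r2[ok], c2[ok])]
    if (any(ok)) {
      j <- match((c2[ok] - 1L) * h + r2[ok], ids)
      edges <- rbind(edges, cbind(which(ok), j))
    }
  }
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  sizes <- tabulate(comp)
  keep <- which(sizes >= 4)
  if (length(keep) < expected_count)
    stopf("detect_fiducials: found %d of %d markers", length(keep), expected_count)
  keep <- keep[order(sizes[keep], decreasing = TRUE)][seq_len(expected_count)]
  # centroids weighted by intensity above the window floor: pixels near the
  # threshold contribute ~0 weight, so the estimate varies smoothly with
  # sub-pixel marker position instead of jumping as rim pixels enter/leave
  cent <- t(vapply(keep, function(ci) {
    px <- comp == ci
    wgt <- img[ids[px]] - intensity_window[1]
    if (sum(wgt) <= 0) wgt <- wgt + 1
    c(sum(cc[px] * wgt), sum(rr[px] * wgt)) / sum(wgt)
  }, numeric(2)))
  ord <- order(cent[, 2], cent[, 1])
  structure(list(points = cent[ord, , drop = FALSE],
                 labels = seq_len(expected_count)),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("<fiducial_set> %d markers\n", nrow(x$points)))
  print(cbind(label = x$labels, x = x$points[, 1], y = x$points[, 2]))
  invisible(x)
}

fiducial_points <- function(x) {
  if (inherits(x, "fiducial_set")) x$points else matrix(as.numeric(x), ncol = 2)
}

check_not_collinear <- function(p, what) {
  # largest doubled triangle area over the first point and all pairs
  n <- nrow(p)
  area <- 0
  for (i in 2:(n - 1)) for (j in (i + 1):n) {
    a <- p[i, ] - p[1, ]; b <- p[j, ] - p[1, ]
    area <- max(area, abs(a[1] * b[2] - a[2] * b[1]) / 2)
  }
  if (area <= 1e-6)
    stopf("%s: marker points are collinear (max triangle area %g px^2)", what, area)
}

#' Estimate the slice-to-slice affine from matched landmarks
#'
#' Solves `target = T source` in homogeneous coordinates by least squares
#' over matched point pairs. With exactly three non-collinear pairs the
#' solution interpolates exactly (six equations, six unknowns); with more
#' pairs the residual RMS is attached as attribute `"rms"`.
#'
#' @param source,target `fiducial_set`s or n x 2 point matrices, matched
#'   row by row (by label), n >= 3.
#' @return an [affine2d()] with attribute `rms`.
#' @export
estimate_affine <- function(source, target) {
  s <- fiducial_points(source)
  t <- fiducial_points(target)
  if (nrow(s) != nrow(t))
    stopf("estimate_affine: %d source vs %d target points", nrow(s), nrow(t))
  if (nrow(s) < 3) stopf("estimate_affine: need at least 3 matched points")
  check_not_collinear(s, "estimate_affine")
  X <- cbind(s, 1)
  coefs <- qr.solve(X, t)            # 3 x 2; columns are rows of T
  Tm <- rbind(t(coefs), c(0, 0, 1))
  A <- affine2d(Tm)
  res <- X %*% coefs - t
  attr(A, "rms") <- sqrt(mean(rowSums(res^2)))
  A
}

#' Resample a slice through an affine transform
#'
#' Output pixel `(x, y)` takes the bilinear sample of the input at
#' `T^{-1}(x, y)`; sample points outside the input footprint get
#' `fill_value`. Output dimensions equal input dimensions. Bilinear (not
#' bicubic) interpolation keeps the operation monotone, with no overshoot
#' near mask edges.
#'
#' @param image numeric matrix.
#' @param T an [affine2d()].
#' @param fill_value value for out-of-bounds samples.
#' @return matrix of the same dimensions as `image`.
#' @export
resample_slice <- function(image, T, fill_value = 0) {
  stopifnot(inherits(T, "affine2d"))
  img <- as.matrix(image)
  h <- nrow(img); w <- ncol(img)
  Ti <- unclass(affine_inverse(T))
  xs <- rep(seq_len(w), each = h)
  ys <- rep(seq_len(h), times = w)
  sx <- Ti[1, 1] * xs + Ti[1, 2] * ys + Ti[1, 3]
  sy <- Ti[2, 1] * xs + Ti[2, 2] * ys + Ti[2, 3]
  inside <- sx >= 1 & sx <= w & sy >= 1 & sy <= h
  val <- rep(fill_value, h * w)
  if (any(inside)) {
    sx <- sx[inside]; sy <- sy[inside]
    x0 <- pmin(pmax(floor(sx), 1), w - 1)
    y0 <- pmin(pmax(floor(sy), 1), h - 1)
    fx <- sx - x0; fy <- sy - y0
    v00 <- img[cbind(y0, x0)];     v01 <- img[cbind(y0, x0 + 1)]
    v10 <- img[cbind(y0 + 1, x0)]; v11 <- img[cbind(y0 + 1, x0 + 1)]
    val[inside] <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
      fy * ((1 - fx) * v10 + fx * v11)
  }
  matrix(val, h, w)
}

#' Register every slice of a stack to a reference slice
#'
#' Detects fiducial markers on each slice, estimates the affine mapping
#' each slice's markers onto the reference slice's markers, and resamples
#' every slice into the reference frame. The reference slice is returned
#' unchanged (its transform is the identity).
#'
#' @param stack a [slice_stack()] of at least 2 slices.
#' @param reference_index which slice defines the common frame.
#' @param expected_count,intensity_window passed to [detect_fiducials()].
#' @return list with `stack` (registered [slice_stack()]) and `transforms`
#'   (list of [affine2d()], slice to reference frame), each with an `rms`
#'   residual attribute.
#' @export
register_stack <- function(stack, reference_index = 1, expected_count = 3,
                           intensity_window = c(228, 255)) {
  stopifnot(inherits(stack, "slice_stack"))
  nz <- length(stack$images)
  if (nz < 2) stopf("register_stack: need at least 2 slices, got %d", nz)
  if (reference_index < 1 || reference_index > nz)
    stopf("register_stack: reference_index %d out of 1..%d", reference_index, nz)
  fids <- vector("list", nz)
  for (k in seq_len(nz)) {
    fids[[k]] <- tryCatch(
      detect_fiducials(stack$images[[k]], expected_count, intensity_window),
      error = function(e) stopf("register_stack: slice %d: %s", k, conditionMessage(e)))
  }
  ref <- fids[[reference_index]]
  out <- stack
  transforms <- vector("list", nz)
  for (k in seq_len(nz)) {
    if (k == reference_index) {
      A <- affine_identity()
      attr(A, "rms") <- 0
    } else {
      A <- estimate_affine(fids[[k]], ref)     # slice k -> reference frame
      out$images[[k]] <- resample_slice(stack$images[[k]], A)
    }
    transforms[[k]] <- A
  }
  list(stack = out, transforms = transforms)
}

#' Serialize affine transforms to JSON
#'
#' Row-major 3x3 matrices, one per slice.
#' @param transforms list of [affine2d()].
#' @param path output JSON file.
#' @export
write_transforms <- function(transforms, path) {
  jsonlite::write_json(lapply(transforms, function(A)
    as.vector(t(unclass(A)))), path, digits = NA)
  invisible(path)
}
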