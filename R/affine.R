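#' 2D affine transforms in homogeneous coordinates
#'
#' An `affine2d` is a 3x3 matrix `T` with last row (0, 0, 1) acting on
#' homogeneous pixel coordinates `(x, y, 1)`: a point `p` maps to the first
#' two components of `T %*% c(p, 1)`. The x axis runs along image columns
#' and the y axis along rows; pixel centres sit at integer coordinates
#' starting at 1. Three non-collinear matched landmarks determine such a
#' transform exactly, which is why three alignment markers per slice
#' suffice for slice-stack registration.
#'
#' @param matrix numeric 3x3 matrix; last row must be (0, 0, 1) and the
#'   upper-left 2x2 block must be invertible (|det| > 1e-12).
#' @return an object of class `affine2d`.
#' @export
#' @examples
#' A <- affine2d(rbind(c(1, 0, 3), c(0, 1, -2), c(0, 0, 1)))
#' affine_apply(A, cbind(1, 1))  # translated by (3, -2)
affine2d <- function(matrix) {
  m <- as.matrix(matrix)
  if (!is.numeric(m) || !identical(dim(m), c(3L, 3L)) || any(!is.finite(m)))
    stopf("affine2d: need a finite numeric 3x3 matrix")
  if (any(m[3, ] != c(0, 0, 1)))
    stopf("affine2d: last row must be exactly (0, 0, 1)")
  if (abs(det(m[1:2, 1:2])) <= 1e-12)
    stopf("affine2d: upper-left 2x2 block is singular")
  structure(unname(m), class = "affine2d")
}

#' @rdname affine2d
#' @export
affine_identity <- function() affine2d(diag(3))

#' @rdname affine2d
#' @param tx,ty translation in pixels.
#' @export
affine_translation <- function(tx, ty)
  affine2d(rbind(c(1, 0, tx), c(0, 1, ty), c(0, 0, 1)))

#' @rdname affine2d
#' @param degrees rotation angle, counter-clockwise in the (x, y) plane.
#' @param center 2-vector; the fixed point of the rotation.
#' @export
affine_rotation <- function(degrees, center = c(0, 0)) {
  th <- degrees * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  t <- as.numeric(center) - R %*% as.numeric(center)
  affine2d(rbind(cbind(R, t), c(0, 0, 1)))
}

#' @rdname affine2d
#' @param A,B `affine2d` objects; `affine_compose(A, B)` applies `B` first.
#' @export
affine_compose <- function(A, B) affine2d(unclass(A) %*% unclass(B))

#' @rdname affine2d
#' @export
affine_inverse <- function(A) affine2d(solve(unclass(A)))

#' @rdname affine2d
#' @param points n x 2 matrix of (x, y) coordinates.
#' @export
affine_apply <- function(A, points) {
  p <- rbind(t(as.matrix(points)), 1)
  out <- unclass(A) %*% p
  t(out[1:2, , drop = FALSE])
}

#' @export
print.affine2d <- function(x, ...) {
  cat("<affine2d>\n")
  print(unclass(x))
  invisible(x)
}

#' @export
format.affine2d <- function(x, ...) paste(sprintf("%g", unclass(x)), collapse = " ")
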