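#' Locate an iso-point on a cell edge
#'
#' Linear interpolation between two corner samples: the iso-point sits at
#' `P_i + Q (P_j - P_i)` with `Q = (C0 - q_i) / (q_j - q_i)`, the
#' interpolant whose endpoint limits reproduce the corners (`Q = 0` when
#' the first corner already equals the isovalue). `Q` always lands in
#' \[0, 1\] because the table only ever asks for edges whose corner states
#' differ.
#'
#' @param p_i,p_j corner positions (3-vectors, mm).
#' @param q_i,q_j corner values.
#' @param isovalue the contour value.
#' @return list with `Q` and `position`.
#' @export
#' @examples
#' interpolate_edge(c(0, 0, 0), c(1, 0, 0), 0, 1, 0.5)$position  # (0.5, 0, 0)
interpolate_edge <- function(p_i, p_j, q_i, q_j, isovalue) {
  if ((q_i >= isovalue) == (q_j >= isovalue))
    stopf("interpolate_edge: corner states do not differ (internal error)")
  Q <- (isovalue - q_i) / (q_j - q_i)
  list(Q = Q, position = as.numeric(p_i) + Q * (as.numeric(p_j) - as.numeric(p_i)))
}

#' Central-difference gradient of a volume at a grid node
#'
#' The gradient used for vertex normals:
#' `g_x = (D[i+1, j, k] - D[i-1, j, k]) / dx` and likewise for y and z —
#' the central difference written without the conventional factor 2 in the
#' denominator; normals are normalized downstream so the overall scale
#' cancels. At boundary nodes a one-sided difference is substituted and a
#' message is logged.
#'
#' @param vol a [volume3d()].
#' @param ijk integer 3-vector of 1-based grid indices.
#' @return numeric 3-vector (un-normalized gradient).
#' @export
vertex_gradient <- function(vol, ijk) {
  stopifnot(inherits(vol, "volume3d"))
  d <- dim(vol$data)
  ijk <- as.integer(ijk)
  if (any(ijk < 1) || any(ijk > d))
    stopf("vertex_gradient: index out of range")
  if (any(ijk == 1 | ijk == d))
    message("vertex_gradient: boundary node; one-sided difference substituted")
  g <- numeric(3)
  for (a in 1:3) {
    up <- ijk; up[a] <- min(ijk[a] + 1L, d[a])
    dn <- ijk; dn[a] <- max(ijk[a] - 1L, 1L)
    g[a] <- (vol$data[up[1], up[2], up[3]] - vol$data[dn[1], dn[2], dn[3]]) /
      vol$spacing[a]
  }
  g
}

# vectorized gradients at 0-based node linear ids; returns n x 3 plus the
# count of boundary nodes where a one-sided difference was used
node_gradients <- function(A, d, sp, nid0) {
  i <- nid0 %% d[1]
  j <- (nid0 %/% d[1]) %% d[2]
  k <- nid0 %/% (d[1] * d[2])
  g <- matrix(0, length(nid0), 3)
  idx <- cbind(i, j, k)
  nb <- 0L
  for (a in 1:3) {
    up <- pmin(idx[, a] + 1L, d[a] - 1L)
    dn <- pmax(idx[, a] - 1L, 0L)
    nb <- nb + sum(up - dn != 2L)
    iu <- idx; iu[, a] <- up
    id <- idx; id[, a] <- dn
    lin <- function(m) 1 + m[, 1] + d[1] * (m[, 2] + d[2] * m[, 3])
    g[, a] <- (A[lin(iu)] - A[lin(id)]) / sp[a]
  }
  list(g = g, n_boundary = nb)
}

#' Extract an isosurface mesh from a volume
#'
#' Marches every cell of 8 neighbouring samples in raster order. Per
#' cell: classify the corners against the isovalue (>= means inside),
#' look up the triangulation in the case table, place the iso-points on
#' the intersected edges by linear interpolation, and emit triangles in
#' physical mm coordinates (spacing and origin applied). Vertices shared
#' between cells are welded by exact grid-edge identity — no coordinate
#' tolerance — so adjacent cells reference the same vertex. Per-vertex
#' normals come from the central-difference gradient at the two edge
#' endpoints, interpolated with the same weight as the position,
#' normalized, and oriented from high values toward low (outward for a
#' bright-inside volume). Zero-area triangles arising when an iso-point
#' coincides with a corner are dropped and counted.
#'
#' If the volume meets the isovalue in its outermost sample layer the
#' surface is clipped there; a warning recommends `pad = TRUE`, which
#' surrounds the volume with a below-isovalue layer (shifting the origin
#' by one spacing) so the mesh closes.
#'
#' @param vol a [volume3d()].
#' @param isovalue finite contour value; a corner exactly at the isovalue
#'   counts as inside.
#' @param pad logical; pad the volume with a below-isovalue layer first.
#' @return an [iso_mesh()] with attributes `n_dropped_degenerate` and
#'   `n_boundary_gradient`.
#' @export
extract_isosurface <- function(vol, isovalue, pad = FALSE) {
  stopifnot(inherits(vol, "volume3d"))
  if (!is.finite(isovalue)) stopf("extract_isosurface: isovalue must be finite")
  A <- vol$data
  sp <- vol$spacing
  org <- vol$origin
  if (pad) {
    d0 <- dim(A)
    padval <- min(min(A), isovalue) - max(1e-6, 1e-3 * max(1, diff(range(A))))
    B <- array(padval, d0 + 2L)
    B[1 + seq_len(d0[1]), 1 + seq_len(d0[2]), 1 + seq_len(d0[3])] <- A
    A <- B
    org <- org - sp
  } else {
    d0 <- dim(A)
    crosses <- function(face) {
      s <- face >= isovalue
      any(s) && !all(s)
    }
    clipped <- crosses(A[1, , ]) || crosses(A[d0[1], , ]) ||
      crosses(A[, 1, ]) || crosses(A[, d0[2], ]) ||
      crosses(A[, , 1]) || crosses(A[, , d0[3]])
    if (clipped)
      warning("extract_isosurface: the isosurface touches the volume boundary and is clipped there; consider pad = TRUE",
              call. = FALSE)
  }
  d <- dim(A)
  nc <- d - 1L
  offs <- mc_corner_offsets()
  # 8-bit case index for every cell, vectorized over the whole grid
  index <- array(0, dim = nc)
  for (c0 in 0:7) {
    o <- offs[c0 + 1, ]
    sub <- A[o[1] + seq_len(nc[1]), o[2] + seq_len(nc[2]), o[3] + seq_len(nc[3])]
    index <- index + (sub >= isovalue) * 2^c0
  }
  index <- as.integer(index)
  active <- which(index != 0L & index != 255L)
  empty <- iso_mesh(matrix(0, 0, 3), matrix(0L, 0, 3))
  if (length(active) == 0) {
    attr(empty, "n_dropped_degenerate") <- 0L
    attr(empty, "n_boundary_gradient") <- 0L
    return(empty)
  }
  tab <- build_case_table()
  nedges <- lengths(tab)
  caseof <- index[active]
  counts <- nedges[caseof + 1L]
  keep <- counts > 0L
  active <- active[keep]; caseof <- caseof[keep]; counts <- counts[keep]
  tri_cube <- rep.int(active, counts)
  tri_edge <- unlist(tab[caseof + 1L], use.names = FALSE)   # 0-based edges

  # cell coordinates (0-based) of each triangle-corner entry
  ci <- (tri_cube - 1L) %% nc[1]
  cj <- ((tri_cube - 1L) %/% nc[1]) %% nc[2]
  ck <- (tri_cube - 1L) %/% (nc[1] * nc[2])
  ec <- mc_edge_corners()
  eoffA <- offs[ec[, 1] + 1L, , drop = FALSE]               # low corner of edge
  eaxis <- max.col(abs(offs[ec[, 2] + 1L, , drop = FALSE] - eoffA))  # 1..3
  oa <- eoffA[tri_edge + 1L, , drop = FALSE]
  ax <- eaxis[tri_edge + 1L]
  ni <- ci + oa[, 1]; nj <- cj + oa[, 2]; nk <- ck + oa[, 3]
  node0 <- ni + d[1] * (nj + d[2] * nk)                     # 0-based node id
  gid <- (ax - 1L) * prod(d) + node0                        # global edge id

  ugid <- unique(gid)
  vid <- match(gid, ugid)

  # interpolate each welded vertex once
  uax <- ugid %/% prod(d) + 1L
  unode <- ugid %% prod(d)
  step <- c(1L, d[1], d[1] * d[2])
  qa <- A[unode + 1L]
  qb <- A[unode + step[uax] + 1L]
  if (any((qa >= isovalue) == (qb >= isovalue)))
    stopf("extract_isosurface: table requested an edge without a sign change (internal error)")
  Q <- (isovalue - qa) / (qb - qa)
  ui <- unode %% d[1]
  uj <- (unode %/% d[1]) %% d[2]
  uk <- unode %/% (d[1] * d[2])
  pos <- cbind(org[1] + ui * sp[1], org[2] + uj * sp[2], org[3] + uk * sp[3])
  pos[cbind(seq_along(uax), uax)] <- pos[cbind(seq_along(uax), uax)] +
    Q * sp[uax]

  # vertex normals: gradient at both edge endpoints, blended with Q,
  # then normalized and negated so normals run from high values to low
  nodes_needed <- unique(c(unode, unode + step[uax]))
  gr <- node_gradients(A, d, sp, nodes_needed)
  ga <- gr$g[match(unode, nodes_needed), , drop = FALSE]
  gb <- gr$g[match(unode + step[uax], nodes_needed), , drop = FALSE]
  gv <- ga + Q * (gb - ga)
  nrm <- -gv
  len <- sqrt(rowSums(nrm^2))

  tri <- matrix(vid, ncol = 3, byrow = TRUE)
  # drop zero-area triangles where two iso-points coincide (Q hit 0 or 1)
  same <- function(a, b) pos[a, 1] == pos[b, 1] & pos[a, 2] == pos[b, 2] &
    pos[a, 3] == pos[b, 3]
  degen <- tri[, 1] == tri[, 2] | tri[, 2] == tri[, 3] | tri[, 1] == tri[, 3] |
    same(tri[, 1], tri[, 2]) | same(tri[, 2], tri[, 3]) | same(tri[, 1], tri[, 3])
  ndrop <- sum(degen)
  if (ndrop) {
    message(sprintf("extract_isosurface: dropped %d degenerate zero-area triangle(s)", ndrop))
    tri <- tri[!degen, , drop = FALSE]
  }
  # prune vertices no longer referenced
  used <- sort(unique(as.vector(tri)))
  remap <- match(seq_len(nrow(pos)), used)
  tri <- matrix(remap[tri], ncol = 3)
  pos <- pos[used, , drop = FALSE]
  nrm <- nrm[used, , drop = FALSE]
  len <- len[used]

  if (nrow(tri) == 0) {
    attr(empty, "n_dropped_degenerate") <- as.integer(ndrop)
    attr(empty, "n_boundary_gradient") <- as.integer(gr$n_boundary)
    return(empty)
  }

  # degenerate gradients (constant neighbourhood): fall back to the mean
  # geometric normal of the incident triangles
  flat <- which(len < 1e-12)
  if (length(flat)) {
    fn <- triangle_face_normals(list(vertices = pos, triangles = tri))
    acc <- matrix(0, nrow(pos), 3)
    for (cidx in 1:3) {
      for (a in 1:3) {
        s <- rowsum(fn[, a], tri[, cidx])
        acc[as.integer(rownames(s)), a] <- acc[as.integer(rownames(s)), a] + s[, 1]
      }
    }
    nrm[flat, ] <- acc[flat, , drop = FALSE]
    len[flat] <- sqrt(rowSums(nrm[flat, , drop = FALSE]^2))
    still <- flat[len[flat] < 1e-12]
    if (length(still)) {
      nrm[still, ] <- matrix(rep(c(0, 0, 1), length(still)), ncol = 3, byrow = TRUE)
      len[still] <- 1
    }
  }
  nrm <- nrm / len
  if (gr$n_boundary > 0)
    message(sprintf("extract_isosurface: one-sided gradient used at %d boundary node sample(s)", gr$n_boundary))
  mesh <- iso_mesh(pos, tri, nrm)
  attr(mesh, "n_dropped_degenerate") <- as.integer(ndrop)
  attr(mesh, "n_boundary_gradient") <- as.integer(gr$n_boundary)
  attr(mesh, "isovalue") <- isovalue
  mesh
}
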