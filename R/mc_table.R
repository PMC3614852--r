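#' Cube numbering conventions of the marching-cubes kernel
#'
#' Corner `i` (0..7) of the unit marching cell sits at offset
#' `(i & 1, (i >> 1) & 1, (i >> 2) & 1)` along (x, y, z), so the corner
#' bits literally spell the coordinate offsets. The twelve cell edges are
#' numbered by axis:
#'
#' | edge | corners | axis | | edge | corners | axis | | edge | corners | axis |
#' |------|---------|------|-|------|---------|------|-|------|---------|------|
#' | 0 | 0-1 | x | | 4 | 0-2 | y | | 8  | 0-4 | z |
#' | 1 | 2-3 | x | | 5 | 1-3 | y | | 9  | 1-5 | z |
#' | 2 | 4-5 | x | | 6 | 4-6 | y | | 10 | 2-6 | z |
#' | 3 | 6-7 | x | | 7 | 5-7 | y | | 11 | 3-7 | z |
#'
#' `mc_corner_offsets()` returns the 8 x 3 offset matrix (row i = corner
#' i-1) and `mc_edge_corners()` the 12 x 2 matrix of 0-based corner pairs
#' (row e = edge e-1).
#'
#' @return integer matrices as described.
#' @export
mc_corner_offsets <- function() {
  cbind(x = bitwAnd(0:7, 1L),
        y = bitwAnd(bitwShiftR(0:7, 1L), 1L),
        z = bitwAnd(bitwShiftR(0:7, 2L), 1L))
}

#' @rdname mc_corner_offsets
#' @export
mc_edge_corners <- function() {
  m <- rbind(c(0, 1), c(2, 3), c(4, 5), c(6, 7),    # x edges
             c(0, 2), c(1, 3), c(4, 6), c(5, 7),    # y edges
             c(0, 4), c(1, 5), c(2, 6), c(3, 7))    # z edges
  storage.mode(m) <- "integer"
  colnames(m) <- c("a", "b")
  m
}

#' Classify cell corners against an isovalue
#'
#' Corner i gets state 1 when its value is greater than *or equal to* the
#' isovalue and 0 otherwise; a corner exactly at the isovalue counts as
#' inside, with no epsilon perturbation. The states pack into the 8-bit
#' case index `sum(S_i * 2^i)`.
#'
#' @param corner_values numeric vector of 8 finite corner samples,
#'   ordered by the corner numbering of [mc_corner_offsets()].
#' @param isovalue finite scalar.
#' @return list with `states` (integer 8-vector) and `index` (0..255).
#' @export
#' @examples
#' classify_corners(rep(0, 8), 0.5)$index   # 0
#' classify_corners(rep(1, 8), 0.5)$index   # 255
classify_corners <- function(corner_values, isovalue) {
  q <- as.numeric(corner_values)
  if (length(q) != 8 || any(!is.finite(q)) || !is.finite(isovalue))
    stopf("classify_corners: need 8 finite corner values and a finite isovalue")
  s <- as.integer(q >= isovalue)
  list(states = s, index = as.integer(sum(s * 2^(0:7))))
}

# the 24 proper rotations of the cube, as permutations of corners 0..7:
# rots[[r]][c + 1] is the image of corner c. Generated from the signed
# permutation matrices with determinant +1 acting about the cube centre.
cube_rotations <- function() {
  offs <- mc_corner_offsets()
  key <- offs %*% c(1, 2, 4)                # corner index from offsets
  rots <- list()
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  for (p in perms3) for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
    R <- matrix(0, 3, 3)
    R[1, p[1]] <- s1; R[2, p[2]] <- s2; R[3, p[3]] <- s3
    if (round(det(R)) != 1) next
    img <- t(R %*% (t(offs) - 0.5) + 0.5)   # rotated offsets, still 0/1
    rots[[length(rots) + 1]] <- as.integer(round(img) %*% c(1, 2, 4))
  }
  rots
}

rotate_case_index <- function(index, perm) {
  out <- 0L
  for (c in 0:7) if (bitwAnd(bitwShiftR(index, c), 1L))
    out <- out + bitwShiftL(1L, perm[c + 1])
  out
}

# induced permutation of edges 0..11: eperm[e + 1] = image of edge e
edge_permutation <- function(perm) {
  ec <- mc_edge_corners()
  lookup <- apply(ec, 1, paste, collapse = "-")
  vapply(seq_len(12), function(e) {
    ab <- sort(perm[ec[e, ] + 1])
    match(paste(ab, collapse = "-"), lookup) - 1L
  }, integer(1))
}

#' The 15 base-case tessellations
#'
#' One representative per equivalence class of the 256 corner
#' configurations under cube rotations combined with complementation
#' (representatives chosen with minimal set-corner count, then minimal
#' index). Each entry is a flat integer vector of edge indices, three per
#' triangle, wound so that triangle normals point from the S = 1 (>=
#' isovalue) side toward the S = 0 side. These are the classic
#' single-sheet tessellations; [build_case_table()] expands them to all
#' 256 configurations.
#'
#' @return named list of 15 integer vectors; names are the case indices.
#' @export
mc_base_cases <- function() {
  list(
    `0`   = integer(0),
    `1`   = c(0L, 4L, 8L),
    `3`   = c(5L, 4L, 8L, 9L, 5L, 8L),
    `6`   = c(5L, 0L, 9L, 1L, 10L, 4L),
    `7`   = c(5L, 1L, 10L, 5L, 10L, 9L, 9L, 10L, 8L),
    `15`  = c(9L, 11L, 8L, 11L, 10L, 8L),
    `22`  = c(9L, 5L, 0L, 8L, 6L, 2L, 1L, 10L, 4L),
    `23`  = c(2L, 10L, 6L, 9L, 10L, 2L, 9L, 1L, 10L, 9L, 5L, 1L),
    `24`  = c(5L, 11L, 1L, 8L, 6L, 2L),
    `25`  = c(4L, 6L, 2L, 4L, 2L, 0L, 5L, 11L, 1L),
    `27`  = c(1L, 9L, 11L, 1L, 6L, 9L, 1L, 4L, 6L, 6L, 2L, 9L),
    `29`  = c(5L, 11L, 10L, 5L, 10L, 2L, 5L, 2L, 0L, 6L, 2L, 10L),
    `30`  = c(2L, 8L, 6L, 9L, 10L, 0L, 9L, 11L, 10L, 10L, 4L, 0L),
    `60`  = c(9L, 8L, 7L, 8L, 6L, 7L, 11L, 4L, 5L, 11L, 10L, 4L),
    `105` = c(3L, 6L, 10L, 5L, 11L, 1L, 0L, 4L, 8L, 2L, 7L, 9L)
  )
}

# package-local cache: the table is deterministic, build it once
.slicemesh_cache <- new.env(parent = emptyenv())

#' Build the 256-entry marching-cubes case table
#'
#' Expands the 15 base cases of [mc_base_cases()] under the 24 proper
#' rotations of the cube; configurations not reachable by rotation take
#' the entry of their complement (index `255 - i`) with reversed triangle
#' winding, which keeps the same intersected-edge set while flipping
#' orientation. Construction is deterministic and self-checking: every
#' index must be assigned, entries 0 and 255 must be empty and all others
#' non-empty, and every entry's edge set must equal exactly the set of
#' edges whose corner states differ.
#'
#' @return list of 256 integer vectors (entry `i + 1` is configuration
#'   `i`), each a flat vector of edge indices, three per triangle.
#' @export
build_case_table <- function() {
  if (!is.null(.slicemesh_cache$case_table)) return(.slicemesh_cache$case_table)
  rots <- cube_rotations()
  eperms <- lapply(rots, edge_permutation)
  base <- mc_base_cases()
  entries <- vector("list", 256)
  for (nm in names(base)) {
    rep_i <- as.integer(nm)
    tri <- base[[nm]]
    for (r in seq_along(rots)) {
      mi <- rotate_case_index(rep_i, rots[[r]])
      if (is.null(entries[[mi + 1]]))
        entries[[mi + 1]] <- eperms[[r]][tri + 1]
    }
  }
  for (mi in 0:255) {
    if (is.null(entries[[mi + 1]])) {
      src <- entries[[256 - mi]]
      if (is.null(src))
        stopf("build_case_table: configuration %d unassigned — broken base case", mi)
      flip <- src
      if (length(src)) {
        k <- seq(1, length(src), by = 3)
        flip[k + 1] <- src[k + 2]
        flip[k + 2] <- src[k + 1]
      }
      entries[[mi + 1]] <- flip
    }
  }
  ec <- mc_edge_corners()
  for (mi in 0:255) {
    used <- sort(unique(entries[[mi + 1]]))
    bits <- bitwAnd(bitwShiftR(mi, 0:7), 1L)
    want <- which(bits[ec[, 1] + 1] != bits[ec[, 2] + 1]) - 1L
    if (!identical(as.integer(used), as.integer(want)))
      stopf("build_case_table: configuration %d references wrong edges", mi)
  }
  if (length(entries[[1]]) || length(entries[[256]]))
    stopf("build_case_table: configurations 0 and 255 must be empty")
  .slicemesh_cache$case_table <- entries
  entries
}

#' Census of the marching-cubes case space
#'
#' Brute-force enumeration of the 256 corner-sign configurations of a
#' cube: counts the configurations that are not all-below (2^8 - 1 = 255
#' of them) and partitions all 256 into equivalence classes under the 24
#' proper rotations combined with global state complementation, counting
#' the orbits (the classic reduction to 15 unique cases, the empty
#' configuration included). The enumeration is independent of
#' [build_case_table()]'s expansion loop.
#'
#' @return list with `non_all_below` (255) and `unique_cases` (15), both
#'   computed, not assumed.
#' @export
mc_case_counts <- function() {
  # a configuration is "all below" iff no corner bit is set
  non_empty <- sum(vapply(0:255, function(i) any(bitwAnd(bitwShiftR(i, 0:7), 1L) == 1L),
                          logical(1)))
  rots <- cube_rotations()
  seen <- logical(256)
  orbits <- 0L
  for (i in 0:255) {
    if (seen[i + 1]) next
    orbits <- orbits + 1L
    frontier <- i
    while (length(frontier)) {
      nxt <- integer(0)
      for (x in frontier) {
        if (seen[x + 1]) next
        seen[x + 1] <- TRUE
        imgs <- vapply(rots, function(p) rotate_case_index(x, p), integer(1))
        nxt <- c(nxt, imgs, 255L - x)
      }
      frontier <- unique(nxt[!seen[nxt + 1]])
    }
  }
  list(non_all_below = non_empty, unique_cases = orbits)
}

#' Export the case table as JSON for inspection
#'
#' @param path output file.
#' @export
write_case_table <- function(path) {
  tab <- build_case_table()
  jsonlite::write_json(lapply(tab, function(e)
    if (length(e)) matrix(e, ncol = 3, byrow = TRUE) else matrix(0L, 0, 3)),
    path, digits = NA)
  invisible(path)
}
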