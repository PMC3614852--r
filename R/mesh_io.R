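#' Triangle surface meshes
#'
#' An `iso_mesh` is the final artifact of the reconstruction pipeline:
#' vertex positions in mm, triangles as 1-based vertex-index triples, and
#' optional unit per-vertex normals. Triangle indices must reference
#' existing vertices and no triangle may repeat a vertex.
#'
#' @param vertices n x 3 numeric matrix of positions (mm).
#' @param triangles m x 3 integer matrix of vertex indices (1-based).
#' @param normals optional n x 3 matrix of unit vectors (|n| = 1 within 1e-6).
#' @return object of class `iso_mesh`.
#' @export
iso_mesh <- function(vertices, triangles, normals = NULL) {
  v <- matrix(as.numeric(vertices), ncol = 3)
  tr <- matrix(as.integer(triangles), ncol = 3)
  if (nrow(tr) > 0) {
    if (any(tr < 1) || any(tr > nrow(v)))
      stopf("iso_mesh: triangle indices out of range 1..%d", nrow(v))
    if (any(tr[, 1] == tr[, 2] | tr[, 2] == tr[, 3] | tr[, 1] == tr[, 3]))
      stopf("iso_mesh: a triangle repeats a vertex index")
  }
  if (!is.null(normals)) {
    normals <- matrix(as.numeric(normals), ncol = 3)
    if (nrow(normals) != nrow(v))
      stopf("iso_mesh: need one normal per vertex")
    nn <- sqrt(rowSums(normals^2))
    if (nrow(normals) && any(abs(nn - 1) > 1e-6))
      stopf("iso_mesh: normals must be unit vectors (max |1-|n|| = %g)",
            max(abs(nn - 1)))
  }
  structure(list(vertices = unname(v), triangles = unname(tr),
                 normals = if (!is.null(normals)) unname(normals)),
            class = "iso_mesh")
}

#' @export
print.iso_mesh <- function(x, ...) {
  cat(sprintf("<iso_mesh> %d vertices, %d triangles%s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (!is.null(x$normals)) ", with normals" else ""))
  invisible(x)
}

triangle_face_normals <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2))
  ok <- len > 1e-300
  n[ok, ] <- n[ok, , drop = FALSE] / len[ok]
  n[!ok, ] <- 0
  n
}

mesh_format_of <- function(path, format = NULL) {
  if (!is.null(format))
    return(match.arg(format, c("stl_binary", "obj", "ply_ascii")))
  switch(tolower(tools::file_ext(path)),
         stl = "stl_binary",
         obj = "obj",
         ply = "ply_ascii",
         stopf("write_mesh: cannot infer format from '%s'; pass 'format'", path))
}

#' Write a mesh to STL (binary), OBJ, or ASCII PLY
#'
#' All writers are deterministic: fixed header text, no timestamps, so the
#' same mesh always produces byte-identical files. A binary STL is the
#' 80-byte header, a little-endian uint32 triangle count, and one 50-byte
#' record per triangle (facet normal recomputed from the vertex winding,
#' three float32 vertices, a zero attribute word); an empty mesh yields a
#' valid 84-byte file with a warning.
#'
#' @param mesh an [iso_mesh()].
#' @param path output file; extension `.stl`/`.obj`/`.ply` selects the
#'   format when `format` is NULL.
#' @param format one of `"stl_binary"`, `"obj"`, `"ply_ascii"`.
#' @return invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "iso_mesh"))
  format <- mesh_format_of(path, format)
  if (nrow(mesh$triangles) == 0)
    warning("write_mesh: mesh has zero triangles; writing a valid empty file",
            call. = FALSE)
  switch(format,
         stl_binary = write_stl_binary(mesh, path),
         obj = write_obj(mesh, path),
         ply_ascii = write_ply_ascii(mesh, path))
  invisible(path)
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- raw(80)
  txt <- charToRaw("slicemesh binary STL")
  header[seq_along(txt)] <- txt
  writeBin(header, con)
  m <- nrow(mesh$triangles)
  writeBin(as.integer(m), con, size = 4, endian = "little")
  if (m == 0) return(invisible(path))
  fn <- triangle_face_normals(mesh)
  v1 <- mesh$vertices[mesh$triangles[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$triangles[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$triangles[, 3], , drop = FALSE]
  vals <- as.numeric(t(cbind(fn, v1, v2, v3)))      # 12 floats per record
  fl <- writeBin(vals, raw(), size = 4, endian = "little")
  rec <- matrix(as.raw(0), nrow = 50, ncol = m)
  rec[1:48, ] <- matrix(fl, nrow = 48)
  writeBin(as.vector(rec), con)
  invisible(path)
}

write_obj <- function(mesh, path) {
  lines <- c("# slicemesh OBJ",
             sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]))
  if (!is.null(mesh$normals))
    lines <- c(lines, sprintf("vn %.9g %.9g %.9g",
                              mesh$normals[, 1], mesh$normals[, 2], mesh$normals[, 3]))
  tr <- mesh$triangles
  if (nrow(tr)) {
    lines <- c(lines, if (is.null(mesh$normals))
      sprintf("f %d %d %d", tr[, 1], tr[, 2], tr[, 3])
    else
      sprintf("f %d//%d %d//%d %d//%d", tr[, 1], tr[, 1], tr[, 2], tr[, 2],
              tr[, 3], tr[, 3]))
  }
  writeLines(lines, path)
}

write_ply_ascii <- function(mesh, path) {
  nv <- nrow(mesh$vertices)
  hasn <- !is.null(mesh$normals)
  head <- c("ply", "format ascii 1.0", "comment slicemesh",
            sprintf("element vertex %d", nv),
            "property float x", "property float y", "property float z",
            if (hasn) c("property float nx", "property float ny", "property float nz"),
            sprintf("element face %d", nrow(mesh$triangles)),
            "property list uchar int vertex_indices", "end_header")
  vdat <- if (hasn) cbind(mesh$vertices, mesh$normals) else mesh$vertices
  vlines <- if (nv) apply(vdat, 1, function(r) paste(sprintf("%.9g", r), collapse = " ")) else character(0)
  tr <- mesh$triangles
  flines <- if (nrow(tr)) sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L) else character(0)
  writeLines(c(head, vlines, flines), path)
}

#' Read a mesh written by [write_mesh()]
#'
#' STL stores unindexed triangle soup; on ingestion, exactly coincident
#' vertices are welded back into an indexed mesh. OBJ and PLY retain their
#' indexing. Vertex coordinates round-trip at float32 precision for STL and
#' at 9 significant digits for the ASCII formats.
#'
#' @inheritParams write_mesh
#' @return an [iso_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  format <- mesh_format_of(path, format)
  switch(format,
         stl_binary = read_stl_binary(path),
         obj = read_obj(path),
         ply_ascii = read_ply_ascii(path))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, raw(), 80))
  m <- readBin(con, integer(), 1, size = 4, endian = "little")
  if (m == 0) return(iso_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  rec <- readBin(con, raw(), 50 * m)
  rec <- matrix(rec, nrow = 50)
  fl <- readBin(as.vector(rec[1:48, ]), numeric(), 12 * m, size = 4,
                endian = "little")
  fl <- matrix(fl, nrow = 12)                # cols = triangles
  corners <- matrix(NA_real_, 3 * m, 3)
  corners[seq(1, 3 * m, 3), ] <- t(fl[4:6, , drop = FALSE])
  corners[seq(2, 3 * m, 3), ] <- t(fl[7:9, , drop = FALSE])
  corners[seq(3, 3 * m, 3), ] <- t(fl[10:12, , drop = FALSE])
  key <- paste(corners[, 1], corners[, 2], corners[, 3])
  idx <- match(key, unique(key))
  verts <- corners[!duplicated(key), , drop = FALSE]
  iso_mesh(verts, matrix(idx, ncol = 3, byrow = TRUE))
}

read_obj <- function(path) {
  lines <- readLines(path)
  vs <- lines[startsWith(lines, "v ")]
  ns <- lines[startsWith(lines, "vn ")]
  fs <- lines[startsWith(lines, "f ")]
  num3 <- function(x, skip) {
    t(vapply(strsplit(trimws(substring(x, skip)), "[[:space:]]+"),
             function(p) as.numeric(p[1:3]), numeric(3)))
  }
  v <- num3(vs, 3)
  n <- if (length(ns)) num3(ns, 4) else NULL
  tr <- t(vapply(strsplit(trimws(substring(fs, 3)), "[[:space:]]+"),
                 function(p) as.integer(sub("/.*", "", p[1:3])), integer(3)))
  iso_mesh(v, tr, n)
}

read_ply_ascii <- function(path) {
  lines <- readLines(path)
  endh <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face ", lines, value = TRUE)[1]))
  hasn <- any(grepl("^property float nx$", lines[seq_len(endh)]))
  vlines <- lines[endh + seq_len(nv)]
  flines <- lines[endh + nv + seq_len(nf)]
  vdat <- if (nv) t(vapply(strsplit(vlines, " "), as.numeric,
                           numeric(if (hasn) 6 else 3))) else matrix(0, 0, if (hasn) 6 else 3)
  tr <- if (nf) t(vapply(strsplit(flines, " "),
                         function(p) as.integer(p[2:4]) + 1L, integer(3))) else matrix(0L, 0, 3)
  iso_mesh(vdat[, 1:3, drop = FALSE], tr,
           if (hasn && nv) vdat[, 4:6, drop = FALSE])
}
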