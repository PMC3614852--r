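# Independent reference isosurfacer (classic marching cubes as shipped with
# scikit-image), driven through inst/oracle/reference_isosurface.py. Used to
# cross-check the kernel on batches of small random volumes.

# three families of seeded random 8^3 volumes:
#  - "rich": mixtures of three Gaussian blobs contoured mid-range, giving
#    surfaces that exercise many case-table entries;
#  - "cap": a single blob contoured high, giving small simple patches;
#  - "node": iid uniform noise contoured between the largest and
#    second-largest sample, so exactly one node is above the level and the
#    tessellation (one corner clipped per incident cell) is forced — the
#    shared-convention family for exact volume comparison.
oracle_volume <- function(seed, mode = c("rich", "cap", "node")) {
  mode <- match.arg(mode)
  set.seed(seed)
  n <- 8
  ax <- seq_len(n) - (n + 1) / 2
  X <- array(rep(ax, times = n * n), c(n, n, n))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  if (mode == "rich") {
    f <- array(0, c(n, n, n))
    for (b in 1:3) {
      cx <- runif(3, -2.5, 2.5)
      s <- runif(1, 2, 8)
      f <- f + exp(-((X - cx[1])^2 + (Y - cx[2])^2 + (Z - cx[3])^2) / s)
    }
    level <- mean(range(f))
  } else if (mode == "cap") {
    cx <- runif(3, -1.5, 1.5)
    s <- runif(1, 3, 6)
    f <- exp(-((X - cx[1])^2 + (Y - cx[2])^2 + (Z - cx[3])^2) / s)
    q <- as.numeric(quantile(f, 0.97))
    level <- q + 0.6 * (max(f) - q)
  } else {
    f <- array(runif(n^3), c(n, n, n))
    level <- mean(sort(f, decreasing = TRUE)[1:2])
  }
  list(f = f, level = level)
}

oracle_batch <- function(n_rich = 50, n_cap = 25, n_node = 25) {
  c(lapply(seq_len(n_rich), oracle_volume, mode = "rich"),
    lapply(n_rich + seq_len(n_cap), oracle_volume, mode = "cap"),
    lapply(n_rich + n_cap + seq_len(n_node), oracle_volume, mode = "node"))
}

run_reference_isosurfacer <- function(specs) {
  script <- system.file("oracle", "reference_isosurface.py", package = "slicemesh")
  job <- tempfile(fileext = ".json")
  out <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(volumes = lapply(specs, function(s)
      list(shape = dim(s$f), data = as.vector(s$f), level = s$level))),
    job, auto_unbox = TRUE, digits = NA)
  status <- system2("python", c(script, job, out))
  stopifnot(status == 0)
  res <- jsonlite::read_json(out, simplifyVector = FALSE)
  lapply(res, function(r) {
    if (length(r$verts) == 0)
      return(list(verts = matrix(0, 0, 3), faces = matrix(0L, 0, 3), volume = 0))
    list(verts = do.call(rbind, lapply(r$verts, unlist)),
         faces = do.call(rbind, lapply(r$faces, unlist)) + 1L,
         volume = r$volume)
  })
}

# grid-edge identity of vertices lying on grid edges (index coordinates).
# Vertices within 1e-4 of a grid node are excluded: the reference works in
# float32 and snaps such near-degenerate crossings to the node.
grid_edge_keys <- function(verts, tol = 1e-4) {
  if (nrow(verts) == 0) return(character(0))
  fr <- abs(verts - round(verts)) > tol
  keep <- rowSums(fr) == 1
  v <- verts[keep, , drop = FALSE]
  fr <- fr[keep, , drop = FALSE]
  if (nrow(v) == 0) return(character(0))
  base <- floor(v + tol)
  sort(unique(sprintf("%d:%d,%d,%d", max.col(fr), base[, 1], base[, 2], base[, 3])))
}

# winding-insensitive triangle multiset key
triangle_keys <- function(verts, faces) {
  if (nrow(faces) == 0) return(character(0))
  sort(apply(faces, 1, function(t)
    paste(sort(sprintf("%.9f,%.9f,%.9f",
                       verts[t, 1], verts[t, 2], verts[t, 3])), collapse = "|")))
}
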