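test_that("volumes without crossings give empty meshes", {
  vol <- volume3d(array(1, c(4, 4, 4)), c(1, 1, 1))
  mesh <- quiet_extract(vol, 5)
  expect_equal(nrow(mesh$triangles), 0)
  expect_equal(nrow(mesh$vertices), 0)
})

test_that("an isolated hot sample meshes to an octahedron", {
  d <- array(0, c(5, 5, 5))
  d[3, 3, 3] <- 1
  mesh <- quiet_extract(volume3d(d, c(1, 1, 1)), 0.5)
  expect_equal(nrow(mesh$triangles), 8)
  expect_equal(nrow(mesh$vertices), 6)
  cen <- watertight_check(mesh)
  expect_true(cen$is_closed)
  expect_equal(euler_characteristic(mesh), 2)
  # vertices sit at the half-way crossings around the hot sample
  expect_equal(sort(unique(round(as.vector(mesh$vertices), 6))), c(1.5, 2, 2.5))
})

test_that("a corner value exactly at the isovalue collapses to dropped slivers", {
  d <- array(0, c(5, 5, 5))
  d[3, 3, 3] <- 1
  # isovalue 1: the hot corner is inside by the >= rule, Q = 1 everywhere,
  # so all crossings coincide at the hot node and every triangle degenerates
  expect_message(mesh <- suppressWarnings(
    extract_isosurface(volume3d(d, c(1, 1, 1)), 1)), "degenerate")
  expect_equal(nrow(mesh$triangles), 0)
  expect_equal(attr(mesh, "n_dropped_degenerate"), 8L)
})

test_that("phantom surfaces are watertight with the right topology", {
  sphere <- quiet_extract(generate_field(sphere_spec()), 0)
  expect_true(watertight_check(sphere)$is_closed)
  expect_equal(euler_characteristic(sphere), 2)

  torus <- quiet_extract(generate_field(torus_spec()), 0)
  expect_true(watertight_check(torus)$is_closed)
  expect_equal(euler_characteristic(torus), 0)

  tube <- quiet_extract(generate_field(tube_spec()), 0)
  expect_true(watertight_check(tube)$is_closed)
  expect_equal(euler_characteristic(tube), 2)   # capped tube = sphere topology
})

test_that("gradient normals on a sphere point along the radius", {
  spec <- sphere_spec()
  mesh <- quiet_extract(generate_field(spec), 0)
  radial <- sweep(mesh$vertices, 2, spec$shape_params$center)
  radial <- radial / sqrt(rowSums(radial^2))
  cosang <- rowSums(mesh$normals * radial)
  # distance field is high outside: normals (high -> low) point inward
  expect_true(all(cosang < 0))
  ang <- acos(pmin(1, -cosang)) * 180 / pi
  expect_lt(mean(ang), 2)
})

test_that("translation equivariance: shifting the origin shifts every vertex", {
  vol <- generate_field(sphere_spec(spacing = 2))
  m0 <- quiet_extract(vol, 0)
  t <- c(3.25, -8, 0.5)
  vol2 <- volume3d(vol$data, vol$spacing, vol$origin + t)
  m1 <- quiet_extract(vol2, 0)
  expect_equal(m1$vertices, m0$vertices + matrix(t, nrow(m0$vertices), 3,
                                                 byrow = TRUE))
  expect_identical(m1$triangles, m0$triangles)
})

test_that("complement symmetry: negating field and isovalue flips orientation", {
  set.seed(5)
  s <- oracle_volume(99, "rich")
  va <- volume3d(s$f, c(1, 1, 1))
  vb <- volume3d(-s$f, c(1, 1, 1))
  ma <- quiet_extract(va, s$level)
  mb <- quiet_extract(vb, -s$level)
  # same vertex sets
  key <- function(v) sort(apply(round(v, 9), 1, paste, collapse = ","))
  expect_identical(key(ma$vertices), key(mb$vertices))
  # opposite orientation: normals at matching vertices are anti-parallel
  ia <- order(apply(round(ma$vertices, 9), 1, paste, collapse = ","))
  ib <- order(apply(round(mb$vertices, 9), 1, paste, collapse = ","))
  expect_lt(max(abs(ma$normals[ia, ] + mb$normals[ib, ])), 1e-9)
  # and the winding flips with the orientation: signed volumes change sign
  signed_vol <- function(m) {
    v1 <- m$vertices[m$triangles[, 1], , drop = FALSE]
    v2 <- m$vertices[m$triangles[, 2], , drop = FALSE]
    v3 <- m$vertices[m$triangles[, 3], , drop = FALSE]
    cr <- cbind(v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2],
                v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3],
                v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
    sum(rowSums(v1 * cr)) / 6
  }
  expect_lt(signed_vol(ma) * signed_vol(mb), 0)
})

test_that("sphere volume error shrinks monotonically with resolution", {
  err <- sapply(c(2, 1, 0.5), function(h) {
    mesh <- quiet_extract(generate_field(sphere_spec(spacing = h)), 0)
    abs(suppressMessages(enclosed_volume(mesh)) - (4 / 3) * pi * 1000)
  })
  expect_true(all(diff(err) < 0))
})

test_that("surfaces touching the boundary are clipped with a warning; padding closes them", {
  d <- array(0, c(6, 6, 6))
  d[1:6, 2:5, 2:5] <- 255                       # bright bar spanning x
  vol <- volume3d(d, c(1, 1, 1))
  expect_warning(m_raw <- suppressMessages(extract_isosurface(vol, 127.5)),
                 "pad")
  expect_gt(watertight_check(m_raw)$boundary_edge_count, 0)
  m_pad <- quiet_extract(vol, 127.5, pad = TRUE)
  expect_true(watertight_check(m_pad)$is_closed)
  expect_equal(euler_characteristic(m_pad), 2)
  expect_gt(suppressMessages(enclosed_volume(m_pad)), 5 * 3 * 3)
})

test_that("per-cell intersected edges equal the sign-change edges of the cell", {
  # white-box invariant behind the oracle comparison: a cell's emitted
  # vertices lie exactly on the edges where its corner states differ
  s <- oracle_volume(7, "rich")
  vol <- volume3d(s$f, c(1, 1, 1))
  mesh <- quiet_extract(vol, s$level)
  keys <- grid_edge_keys(mesh$vertices)
  offs <- mc_corner_offsets()
  ec <- mc_edge_corners()
  eax <- max.col(abs(offs[ec[, 2] + 1, ] - offs[ec[, 1] + 1, ]))
  expected <- character(0)
  d <- dim(s$f)
  for (i in 1:(d[1] - 1)) for (j in 1:(d[2] - 1)) for (k in 1:(d[3] - 1)) {
    q <- sapply(0:7, function(c0)
      s$f[i + offs[c0 + 1, 1], j + offs[c0 + 1, 2], k + offs[c0 + 1, 3]])
    st <- q >= s$level
    for (e in 1:12) {
      if (st[ec[e, 1] + 1] != st[ec[e, 2] + 1]) {
        base <- c(i, j, k) - 1 + offs[ec[e, 1] + 1, ]
        expected <- c(expected,
                      sprintf("%d:%d,%d,%d", eax[e], base[1], base[2], base[3]))
      }
    }
  }
  expect_identical(keys, sort(unique(expected)))
})
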