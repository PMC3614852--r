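test_that("slice stacks round-trip through PNG files and natural ordering", {
  st <- generate_slice_stack(marked_stack_spec())
  dir <- withr::local_tempdir()
  write_stack(st, dir)
  back <- read_stack(dir)
  expect_equal(back$pixel_size, st$pixel_size)
  expect_equal(back$slice_spacing, st$slice_spacing)
  for (k in seq_along(st$images))
    expect_lt(max(abs(back$images[[k]] - st$images[[k]])), 1e-9)

  # natural filename order, not lexicographic
  expect_equal(natural_order(c("slice_10.png", "slice_2.png", "slice_1.png")),
               c(3, 2, 1))
  dir2 <- withr::local_tempdir()
  img <- matrix(0, 8, 8)
  png::writePNG(img, file.path(dir2, "slice_2.png"))
  png::writePNG(img + 1, file.path(dir2, "slice_10.png"))
  back2 <- read_stack(dir2, pixel_size = 1, slice_spacing = 1)
  expect_equal(back2$names, c("slice_2.png", "slice_10.png"))
  expect_equal(back2$images[[2]][1, 1], 255)
})

test_that("RGB slices ingest as ITU-R 601 luminance", {
  dir <- withr::local_tempdir()
  red <- array(0, c(6, 6, 3))
  red[, , 1] <- 1
  png::writePNG(red, file.path(dir, "a_0.png"))
  png::writePNG(red, file.path(dir, "a_1.png"))
  st <- read_stack(dir, pixel_size = 1, slice_spacing = 1)
  expect_equal(unique(as.vector(st$images[[1]])), 0.299 * 255, tolerance = 1e-9)
})

test_that("stack ingestion rejects malformed input", {
  dir <- withr::local_tempdir()
  png::writePNG(matrix(0, 4, 4), file.path(dir, "s_0.png"))
  expect_error(read_stack(dir), "at least 2")
  png::writePNG(matrix(0, 5, 4), file.path(dir, "s_1.png"))
  expect_error(read_stack(dir), "s_1.png")
  png::writePNG(matrix(0, 4, 4), file.path(dir, "s_2.jpg"))
  expect_error(read_stack(file.path(dir, c("s_0.png", "s_2.jpg"))), "JPEG")
})

test_that("binary STL obeys the 50-byte record layout", {
  cube <- unit_cube_mesh()
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(cube, path)
  expect_identical(file.size(path), 80 + 4 + 12 * 50)

  # empty mesh: a valid 84-byte file with zero count, under a warning
  path2 <- withr::local_tempfile(fileext = ".stl")
  expect_warning(write_mesh(iso_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)), path2),
                 "zero triangles")
  expect_identical(file.size(path2), 84)
  con <- file(path2, "rb"); seek(con, 80)
  expect_identical(readBin(con, integer(), 1, size = 4, endian = "little"), 0L)
  close(con)
})

test_that("meshes round-trip through STL, OBJ and PLY", {
  mesh <- quiet_extract(generate_field(sphere_spec(spacing = 2)), 0)
  # compare per-triangle corner coordinates (STL stores an unindexed
  # triangle soup, so vertex indexing need not survive the round trip);
  # rounding to 1e-4 mm sits safely above float32 precision and below the
  # 1e-5 mm round-trip budget
  corners <- function(m) {
    x <- round(m$vertices[t(m$triangles), , drop = FALSE], 4)
    sort(apply(x, 1, paste, collapse = ","))
  }
  for (fmt in c("stl_binary", "obj", "ply_ascii")) {
    ext <- c(stl_binary = ".stl", obj = ".obj", ply_ascii = ".ply")[[fmt]]
    path <- withr::local_tempfile(fileext = ext)
    write_mesh(mesh, path)
    back <- read_mesh(path)
    expect_equal(nrow(back$triangles), nrow(mesh$triangles), info = fmt)
    expect_identical(corners(back), corners(mesh), info = fmt)
    # deterministic writer: identical input, byte-identical file
    path2 <- withr::local_tempfile(fileext = ext)
    write_mesh(mesh, path2)
    expect_identical(readBin(path, raw(), file.size(path)),
                     readBin(path2, raw(), file.size(path2)))
  }
})

test_that("mesh invariants are enforced at construction", {
  expect_error(iso_mesh(matrix(0, 2, 3), rbind(c(1, 2, 3))), "out of range")
  expect_error(iso_mesh(matrix(rnorm(9), 3), rbind(c(1, 1, 2))), "repeats")
  expect_error(iso_mesh(matrix(rnorm(9), 3), rbind(c(1, 2, 3)),
                        normals = matrix(2, 3, 3)), "unit")
})

test_that("masks binarize on the >= 128 rule and round-trip", {
  dir <- withr::local_tempdir()
  # crafted 3x3 mask with lossy-looking ringing values
  m <- matrix(c(0, 10, 127, 128, 200, 255, 5, 130, 0), 3, byrow = TRUE)
  png::writePNG(m / 255, file.path(dir, "m_0.png"))
  png::writePNG(matrix(0, 3, 3), file.path(dir, "m_1.png"))
  masks <- read_mask_stack(dir)
  expect_equal(masks$images[[1]],
               matrix(c(0, 0, 0, 1, 1, 1, 0, 1, 0), 3, byrow = TRUE))
  expect_true(all(masks$images[[2]] == 0))

  # round trip of a clean mask
  dir2 <- withr::local_tempdir()
  write_mask_stack(masks, dir2)
  again <- read_mask_stack(dir2)
  expect_identical(again$images, masks$images)

  # dimension mismatch against a companion stack
  companion <- slice_stack(list(matrix(0, 5, 5), matrix(0, 5, 5)),
                           pixel_size = 1, slice_spacing = 1)
  expect_error(read_mask_stack(dir, companion), "do not match")
})
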