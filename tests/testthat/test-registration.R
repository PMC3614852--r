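test_that("affine estimation is exact on three matched landmarks", {
  P <- rbind(c(10, 10), c(40, 12), c(12, 38))
  # identity
  A <- estimate_affine(P, P)
  expect_equal(unclass(A), diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  # pure translation
  A <- estimate_affine(P, P + matrix(rep(c(3, -2), each = 3), ncol = 2))
  expect_equal(unclass(A)[1:2, 3], c(3, -2), tolerance = 1e-9)
  expect_equal(unclass(A)[1:2, 1:2], diag(2), tolerance = 1e-9)
  expect_lt(attr(A, "rms"), 1e-9)
  # known shear + scale recovered exactly (6 equations, 6 unknowns)
  M <- affine2d(rbind(c(1.2, 0.3, 5), c(-0.1, 0.9, -7), c(0, 0, 1)))
  A <- estimate_affine(P, affine_apply(M, P))
  expect_lt(max(abs(unclass(A) - unclass(M))), 1e-9)
})

test_that("degenerate landmark sets are rejected", {
  P <- rbind(c(1, 1), c(2, 2), c(3, 3))
  expect_error(estimate_affine(P, P), "collinear")
  expect_error(estimate_affine(rbind(c(1, 1), c(2, 2)), rbind(c(1, 1), c(2, 2))),
               "at least 3")
  expect_error(estimate_affine(rbind(c(1, 1), c(5, 2), c(3, 9)),
                               rbind(c(1, 1), c(5, 2))), "3 source vs 2")
})

test_that("estimation inverts applied transforms (property over seeded draws)", {
  set.seed(123)
  for (i in 1:100) {
    P <- matrix(runif(8, 5, 45), ncol = 2)       # 4 landmarks
    repeat {                                     # ensure non-degenerate
      a <- P[2, ] - P[1, ]; b <- P[3, ] - P[1, ]
      if (abs(a[1] * b[2] - a[2] * b[1]) > 1) break
      P <- matrix(runif(8, 5, 45), ncol = 2)
    }
    Tm <- affine2d(rbind(c(1 + rnorm(1, 0, 0.1), rnorm(1, 0, 0.1), rnorm(1, 0, 3)),
                         c(rnorm(1, 0, 0.1), 1 + rnorm(1, 0, 0.1), rnorm(1, 0, 3)),
                         c(0, 0, 1)))
    Arec <- estimate_affine(affine_apply(Tm, P), P)
    expect_lt(max(abs(unclass(affine_compose(Arec, Tm)) - diag(3))), 1e-9)
  }
})

test_that("affine objects validate and compose correctly", {
  expect_error(affine2d(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 2))), "last row")
  expect_error(affine2d(rbind(c(0, 0, 1), c(0, 0, 2), c(0, 0, 1))), "singular")
  A <- affine_compose(affine_translation(4, -1), affine_rotation(30, c(10, 10)))
  expect_lt(max(abs(unclass(affine_compose(A, affine_inverse(A))) - diag(3))),
            1e-9)
})

test_that("bilinear resampling shifts, fills, and round-trips", {
  img <- matrix(0, 32, 32)
  img[10:20, 10:20] <- 100
  expect_identical(resample_slice(img, affine_identity()), img)

  shifted <- resample_slice(img, affine_translation(5, 0), fill_value = -1)
  expect_equal(shifted[, 6:32], img[, 1:27])    # content moved 5 px in x
  expect_true(all(shifted[, 1:5] == -1))        # vacated band filled

  # T then T^-1 on a smooth image: only interpolation loss remains
  xs <- rep(1:64, each = 64); ys <- rep(1:64, times = 64)
  smooth <- matrix(200 * exp(-((xs - 32)^2 + (ys - 30)^2) / 300), 64, 64)
  A <- affine_compose(affine_translation(2.3, -1.7), affine_rotation(3, c(32, 32)))
  back <- resample_slice(resample_slice(smooth, A), affine_inverse(A))
  interior <- back[16:48, 16:48] - smooth[16:48, 16:48]
  expect_lt(max(abs(interior)), 2)

  # a non-invertible transform is rejected
  singular <- structure(rbind(c(1, 0, 0), c(1, 0, 0), c(0, 0, 1)),
                        class = "affine2d")
  expect_error(resample_slice(img, singular))
})

test_that("marker detection finds phantom fiducials to sub-pixel accuracy", {
  st <- generate_slice_stack(marked_stack_spec())
  truth <- attr(st, "fiducial_truth")[[1]]
  truth <- truth[order(truth[, 2], truth[, 1]), ]
  f <- detect_fiducials(st$images[[1]], 3)
  expect_lt(max(sqrt(rowSums((f$points - truth)^2))), 0.5)

  # blank slice
  expect_error(detect_fiducials(matrix(0, 32, 32), 3), "found 0 of 3")

  # sigma = 5 noise: still within a pixel (seeded)
  stn <- generate_slice_stack(marked_stack_spec(noise = 5, seed = 21))
  truthn <- attr(stn, "fiducial_truth")[[1]]
  truthn <- truthn[order(truthn[, 2], truthn[, 1]), ]
  fn <- detect_fiducials(stn$images[[1]], 3)
  expect_lt(max(sqrt(rowSums((fn$points - truthn)^2))), 1.0)
})

test_that("stack registration recovers per-slice jitter", {
  # jitter-free stack: all transforms are the identity
  st0 <- generate_slice_stack(marked_stack_spec())
  reg0 <- register_stack(st0)
  for (A in reg0$transforms)
    expect_lt(max(abs(unclass(A) - diag(3))), 1e-6)

  # jittered stack: recovered transforms match the inverse jitter
  st <- generate_slice_stack(marked_stack_spec(jitter = list(translation = 2,
                                                             rotation = 1)))
  reg <- register_stack(st)
  jt <- attr(st, "jitter_truth")
  pts <- as.matrix(expand.grid(x = seq(1, 48, by = 6), y = seq(1, 48, by = 6)))
  for (k in 2:length(st$images)) {
    d <- affine_apply(reg$transforms[[k]], pts) -
      affine_apply(affine_inverse(jt[[k]]), pts)
    expect_lt(mean(sqrt(rowSums(d^2))), 0.1)
  }

  # registration reduces per-label marker scatter across slices
  scatter <- function(stack) {
    cents <- lapply(stack$images, function(im) detect_fiducials(im, 3)$points)
    mean(sapply(1:3, function(l) {
      P <- t(sapply(cents, function(p) p[l, ]))
      sqrt(mean(rowSums(sweep(P, 2, colMeans(P))^2)))
    }))
  }
  expect_lt(scatter(reg$stack), scatter(st))

  # degenerate and failing inputs
  one <- slice_stack(list(matrix(0, 8, 8)), pixel_size = 1, slice_spacing = 1)
  expect_error(register_stack(one), "at least 2")
  blankish <- slice_stack(list(st$images[[1]], matrix(0, 48, 48)),
                          pixel_size = 1, slice_spacing = 2)
  expect_error(register_stack(blankish), "slice 2")
})
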