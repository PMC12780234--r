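test_that("severity mapping has its boundary exactly at 5 mm", {
  expect_identical(severity_from_depth(c(0, 0.1, 4.999, 5, 7, NA)),
                   c("none", "mild", "mild", "severe", "severe", "none"))
  expect_identical(severity_from_depth(5), "severe")
  expect_identical(severity_from_depth(3), "mild")
})

test_that("supporting-line depth: rectangle abutting a flat uterus edge", {
  n <- 60; px <- 0.6
  # uterus occupies rows 1..30; plaque 5 px thick just behind it
  ut <- matrix(FALSE, n, n); ut[1:30, 11:50] <- TRUE
  pl <- matrix(FALSE, n, n); pl[31:35, 16:45] <- TRUE
  d <- plaque_depth_slice(ut, pl, c(px, px))
  expect_equal(as.double(d), 3.0, tolerance = 1e-9)
  # empty plaque
  expect_true(is.na(plaque_depth_slice(ut, matrix(FALSE, n, n), c(px, px))))
})

test_that("depth is invariant to in-plane rotation within one voxel", {
  n <- 120; px <- 0.6
  base <- function(theta) {
    ut <- raster_rect(n, px, 18, 36, 12, 14, theta)
    # plaque: 3 mm slab on the +x side of the uterus in rotated coordinates
    co <- (seq_len(n) - 1) * px
    g <- expand.grid(x = co, y = co)
    xr <- (g$x - 18) * cos(theta) + (g$y - 36) * sin(theta)
    yr <- -(g$x - 18) * sin(theta) + (g$y - 36) * cos(theta)
    pl <- matrix(xr > 12 & xr <= 15 & abs(yr) <= 9, n, n)
    as.double(plaque_depth_slice(ut, pl, c(px, px)))
  }
  d0 <- base(0)
  d30 <- base(pi / 6)
  expect_lt(abs(d0 - 3.0), 0.6 + 1e-9)
  expect_lt(abs(d30 - d0), 0.6 + 1e-9)
})

test_that("dilating the plaque outward by k voxels adds ~ k voxels of depth", {
  n <- 60; px <- 0.6
  ut <- matrix(FALSE, n, n); ut[1:30, 11:50] <- TRUE
  depths <- vapply(0:3, function(k) {
    pl <- matrix(FALSE, n, n); pl[31:(35 + k), 16:45] <- TRUE
    as.double(plaque_depth_slice(ut, pl, c(px, px)))
  }, 0)
  expect_equal(diff(depths), rep(px, 3), tolerance = 1e-9)
})

test_that("plaque_depth on a full mask: phantom truth, absence, missing label", {
  s <- generate_phantom(phantom_spec(plaque_depth_mm = 3.0, seed = 23))
  m <- plaque_depth(s$organ_mask)
  expect_lt(abs(m$depth_mm - 3.0), 0.6 + 1e-9)
  expect_identical(m$severity, "mild")
  expect_gt(m$width_mm, 0)
  none <- generate_phantom(phantom_spec(plaque_depth_mm = 0, seed = 23))
  m0 <- plaque_depth(none$organ_mask)
  expect_equal(m0$depth_mm, 0)
  expect_identical(m0$severity, "none")
  bad <- label_mask(array(0L, c(4, 4, 2)), c(1, 1, 1), labels = c(plaque = 6L))
  expect_error(plaque_depth(bad), "uterus")
})

test_that("ellipse fitting recovers circle and ellipse axes within 3%", {
  circ <- raster_ellipse(80, 0.6, 9, 9) # radius 15 px = 9 mm
  f <- fit_ellipse_axes(circ, c(0.6, 0.6))
  expect_lt(abs(f$major_mm - 18) / 18, 0.03)
  expect_lt(abs(f$minor_mm - 18) / 18, 0.03)
  ell <- raster_ellipse(140, 0.6, 30, 12, theta = pi / 7)
  f2 <- fit_ellipse_axes(ell, c(0.6, 0.6))
  expect_lt(abs(f2$major_mm - 60) / 60, 0.03)
  expect_lt(abs(f2$minor_mm - 24) / 24, 0.03)
  blob <- matrix(FALSE, 10, 10); blob[5:6, 5:6] <- TRUE
  expect_error(fit_ellipse_axes(blob, c(0.6, 0.6)), "fewer than 5")
})

test_that("oec_axes picks the largest-area slice and splits components", {
  s <- generate_phantom(phantom_spec(oec_axes_mm = c(36, 22), seed = 29,
                                     noise_sd = 0))
  ax <- oec_axes(s$oec_mask)
  expect_length(ax, 1)
  per_slice <- apply(s$oec_mask$data, 3, sum)
  expect_equal(ax[[1]]$slice_index, which.max(per_slice))
  # two disjoint lesions -> two records ordered by component size
  d <- c(60, 60, 9)
  a1 <- raster_ellipsoid(c(12, 9, 8), c(1, 1, 3))
  arr <- array(0L, d)
  arr[1:dim(a1)[1], 1:dim(a1)[2], 1:dim(a1)[3]] <- as.integer(a1)
  a2 <- raster_ellipsoid(c(6, 5, 5), c(1, 1, 3))
  arr[40 + seq_len(dim(a2)[1]), 40 + seq_len(dim(a2)[2]),
      seq_len(dim(a2)[3])] <- as.integer(a2)
  two <- oec_axes(label_mask(arr, c(1, 1, 3), labels = c(oec = 1L)))
  expect_length(two, 2)
  expect_gt(two[[1]]$major_mm, two[[2]]$major_mm)
  expect_error(oec_axes(label_mask(array(0L, c(4, 4, 2)), c(1, 1, 1),
                                   labels = c(oec = 1L))), "empty")
})

test_that("voxel-counting volume: arithmetic and digitized-ball analytics", {
  m <- array(0L, c(20, 20, 10))
  m[1:10, 1:10, 1:10] <- 1L
  expect_equal(mask_volume(m, c(0.6, 0.6, 6.0)), 1000 * 2.16)
  expect_equal(mask_volume(array(0L, c(4, 4, 4)), c(1, 1, 1)), 0)
  ball <- raster_ball(12, 1)
  expect_lt(abs(mask_volume(ball, c(1, 1, 1)) - 4 / 3 * pi * 12^3) /
              (4 / 3 * pi * 12^3), 0.05)
})

test_that("volume change: identity, empty post, and phantom shrink pair", {
  s <- generate_phantom(phantom_spec(oec_axes_mm = c(36, 24), seed = 31))
  expect_equal(volume_change(s$oec_mask, s$oec_mask)$delta_mm3, 0)
  empty <- label_mask(array(0L, dim(s$oec_mask$data)), s$oec_mask$spacing_mm,
                      labels = c(oec = 1L))
  vc <- volume_change(s$oec_mask, empty)
  expect_equal(vc$delta_mm3, -vc$pre_mm3)
  spec <- phantom_spec(oec_axes_mm = c(36, 24), seed = 31)
  post <- generate_phantom(pelvamp:::shrink_oec_spec(spec, 0.5))
  vc2 <- volume_change(s$oec_mask, post$oec_mask)
  expect_lt(abs(vc2$delta_mm3 - (-0.5 * vc2$pre_mm3)) / vc2$pre_mm3, 0.05)
})
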