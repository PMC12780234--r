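small_spec <- function(...) phantom_spec(image_shape = c(96, 96, 20),
                                         spacing_mm = c(1.2, 1.2, 6),
                                         ...)

test_that("zero plaque depth gives an empty plaque mask and severity none", {
  s <- generate_phantom(small_spec(plaque_depth_mm = 0, seed = 1))
  expect_equal(sum(s$organ_mask$data == organ_labels()[["plaque"]]), 0)
  expect_identical(s$truth$severity, "none")
})

test_that("rasterized plaque depth matches the requested depth within one in-plane voxel", {
  s <- generate_phantom(phantom_spec(plaque_depth_mm = 7.2, seed = 3))
  # brute-force scan on the deepest slice: every plaque pixel's distance to
  # the nearest uterus pixel, extended by the half-voxel footprints
  codes <- organ_labels()
  per_slice <- apply(s$organ_mask$data == codes[["plaque"]], 3, sum)
  k <- which.max(per_slice)
  pl <- which(s$organ_mask$data[, , k] == codes[["plaque"]], arr.ind = TRUE)
  ut <- which(s$organ_mask$data[, , k] == codes[["uterus"]], arr.ind = TRUE)
  sp <- s$organ_mask$spacing_mm
  d2 <- outer(pl[, 1], ut[, 1], "-")^2 + outer(pl[, 2], ut[, 2], "-")^2
  reach <- max(apply(sqrt(d2) * sp[1], 1, min)) + sp[1] # center-to-center + footprint
  expect_lt(abs(reach - 7.2), 0.6 + 1e-9)
  # and the measurement pipeline agrees
  m <- plaque_depth(s$organ_mask)
  expect_lt(abs(m$depth_mm - 7.2), 0.6 + 1e-9)
  expect_identical(m$severity, "severe")
})

test_that("cyst cross-section axes and voxel volume are self-consistent", {
  s <- generate_phantom(phantom_spec(oec_axes_mm = c(40, 25), seed = 5))
  ax <- oec_axes(s$oec_mask)[[1]]
  expect_lt(abs(ax$major_mm - 40) / 40, 0.03)
  expect_lt(abs(ax$minor_mm - 25) / 25, 0.03)
  expect_equal(s$truth$oec_volume_mm3, mask_volume(s$oec_mask))
})

test_that("fixed seed reproduces a bit-identical cohort; n = 1 works", {
  c1 <- generate_cohort(6, seed = 7, image_shape = c(96, 96, 20),
                        spacing_mm = c(1.2, 1.2, 6))
  c2 <- generate_cohort(6, seed = 7, image_shape = c(96, 96, 20),
                        spacing_mm = c(1.2, 1.2, 6))
  expect_identical(c1, c2)
  c3 <- generate_cohort(1, seed = 2, image_shape = c(96, 96, 20),
                        spacing_mm = c(1.2, 1.2, 6))
  expect_length(c3, 1)
})

test_that("cohort adhesion prevalence falls in the binomial 95% band", {
  coh <- generate_cohort(200, seed = 11, image_shape = c(96, 96, 20),
                         spacing_mm = c(1.2, 1.2, 6))
  ids <- vapply(coh, `[[`, "", "patient_id")
  pos <- tapply(vapply(coh, function(s)
    s$truth$adhesion[["uterus-rectum"]], NA), ids, any)
  band <- qbinom(c(0.025, 0.975), length(pos), 0.62) / length(pos)
  expect_gte(mean(pos), band[1])
  expect_lte(mean(pos), band[2])
})

test_that("adhesion deformation strictly decreases the inter-organ gap", {
  flags <- setNames(rep(FALSE, 7), adhesion_locations())
  base <- generate_phantom(small_spec(seed = 9, noise_sd = 0,
                                      adhesion_flags = flags))
  flags[["uterus-rectum"]] <- TRUE
  glued <- generate_phantom(small_spec(seed = 9, noise_sd = 0,
                                       adhesion_flags = flags))
  gap <- function(s) {
    codes <- organ_labels()
    ut <- which(s$organ_mask$data == codes[["uterus"]], arr.ind = TRUE)
    re <- which(s$organ_mask$data == codes[["rectum"]], arr.ind = TRUE)
    sp <- s$organ_mask$spacing_mm
    # nearest center-to-center distance via a coarse sweep over rectum voxels
    re <- re[seq(1, nrow(re), by = 7), , drop = FALSE]
    ut <- ut[seq(1, nrow(ut), by = 7), , drop = FALSE]
    min(sqrt(outer(re[, 1] * sp[1], ut[, 1] * sp[1], "-")^2 +
               outer(re[, 2] * sp[2], ut[, 2] * sp[2], "-")^2 +
               outer(re[, 3] * sp[3], ut[, 3] * sp[3], "-")^2))
  }
  expect_lt(gap(glued), gap(base))
})

test_that("every flagged location deforms without invalidating the sample", {
  for (loc in adhesion_locations()) {
    flags <- setNames(adhesion_locations() == loc, adhesion_locations())
    s <- generate_phantom(small_spec(plaque_depth_mm = 6, seed = 21,
                                     adhesion_flags = flags))
    expect_true(all(organ_labels() %in% unique(as.vector(s$organ_mask$data))),
                info = loc)
  }
})

test_that("a spec whose organs cannot fit the grid is rejected", {
  expect_error(generate_phantom(phantom_spec(image_shape = c(40, 40, 8),
                                             spacing_mm = c(0.6, 0.6, 6))),
               "clip")
  expect_error(phantom_spec(spacing_mm = c(0, 1, 1)), "positive")
  expect_error(phantom_spec(oec_axes_mm = c(10, 20)), "major >= minor")
})
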