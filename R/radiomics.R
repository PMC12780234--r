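#' Names of the 14 shape features, in their fixed order
#'
#' Geometry-only descriptors of a 3D mask: principal-axis shape ratios and
#' lengths, maximum 2D/3D diameters, mesh and voxel volume, sphericity,
#' surface area and surface/volume ratio.
#'
#' @return Character vector of length 14.
#' @export
shape_feature_names <- function() {
  c("elongation", "flatness", "least_axis_mm", "major_axis_mm",
    "minor_axis_mm", "max2d_row_mm", "max2d_col_mm", "max2d_slice_mm",
    "max3d_mm", "mesh_volume_mm3", "voxel_volume_mm3", "sphericity",
    "surface_area_mm2", "surface_volume_ratio")
}

as_binary_mask <- function(mask, spacing_mm) {
  if (inherits(mask, "pv_label_mask")) {
    list(m = mask$data != 0L, sp = mask$spacing_mm)
  } else {
    if (is.null(spacing_mm)) stopf("`spacing_mm` required for a bare array")
    list(m = mask != 0, sp = as.double(spacing_mm))
  }
}

#' Principal axes of a mask
#'
#' Eigen-decomposition of the (population) covariance of the physical
#' voxel-center coordinates. Axis lengths are `4 * sqrt(lambda)`;
#' elongation is `sqrt(lambda2 / lambda1)` and flatness
#' `sqrt(lambda3 / lambda1)`.
#'
#' @param mask `pv_label_mask` or logical/0-1 array.
#' @param spacing_mm spacing for a bare array.
#' @return List with `eigenvalues` (decreasing), `axes` (columns =
#'   eigenvectors), `lengths_mm`, `elongation`, `flatness`.
#' @export
principal_axes <- function(mask, spacing_mm = NULL) {
  b <- as_binary_mask(mask, spacing_mm)
  idx <- which(b$m, arr.ind = TRUE)
  if (nrow(idx) < 4) stopf("mask has fewer than 4 foreground voxels")
  P <- sweep(idx - 1, 2, b$sp, "*")
  Pc <- sweep(P, 2, colMeans(P))
  C <- crossprod(Pc) / nrow(Pc)
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  if (lam[3] <= 1e-12)
    stopf("degenerate (coplanar) mask: zero third principal moment")
  list(eigenvalues = lam, axes = e$vectors,
       lengths_mm = 4 * sqrt(lam),
       elongation = sqrt(lam[2] / lam[1]),
       flatness = sqrt(lam[3] / lam[1]))
}

# smoothing used before isosurfacing; halves sigma for very thin structures
# so the 0.5-level surface always exists
mesh_field <- function(m, pad = 5L) {
  d <- dim(m)
  big <- array(0, d + 2L * pad)
  big[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.double(m)
  sigma <- 1.0
  while (sigma >= 0.2) {
    f <- gaussian_smooth3d(big, sigma)
    if (max(f) >= 0.6) return(f)
    sigma <- sigma / 2
  }
  big # thin sliver: mesh the binary field directly
}

#' Triangulated surface area and mesh volume of a mask
#'
#' The binary mask is padded, Gaussian pre-smoothed (sigma = 1 voxel,
#' reduced automatically for very thin structures) and its 0.5-level
#' isosurface triangulated by marching tetrahedra in physical coordinates;
#' volume is computed by the divergence theorem over the closed mesh. The
#' pre-smoothing removes the voxelization staircase that would otherwise
#' bias the area of smooth structures upward by several percent.
#'
#' @inheritParams principal_axes
#' @return List with `surface_area_mm2` and `mesh_volume_mm3`.
#' @export
mesh_surface <- function(mask, spacing_mm = NULL) {
  b <- as_binary_mask(mask, spacing_mm)
  if (!any(b$m)) stopf("empty mask has no surface")
  f <- mesh_field(b$m)
  av <- .cpp_mesh_area_volume(as.double(f), as.integer(dim(f)),
                              as.double(b$sp), 0.5)
  list(surface_area_mm2 = av[1], mesh_volume_mm3 = av[2])
}

# boundary voxel centers in physical mm together with their grid indices
boundary_points <- function(m, sp) {
  idx <- which(boundary_voxels(m), arr.ind = TRUE)
  list(idx = idx, mm = sweep(idx - 1, 2, sp, "*"))
}

max_diameters <- function(m, sp) {
  bp <- boundary_points(m, sp)
  if (nrow(bp$idx) == 0) return(c(row = 0, col = 0, slice = 0, max3d = 0))
  max3d <- .cpp_max_pairwise(bp$mm)
  per_plane <- function(fix_axis) {
    keep <- setdiff(1:3, fix_axis)
    best <- 0
    for (g in unique(bp$idx[, fix_axis])) {
      rows <- bp$idx[, fix_axis] == g
      if (sum(rows) < 2) next
      best <- max(best, .cpp_max_pairwise(bp$mm[rows, keep, drop = FALSE]))
    }
    best
  }
  c(row = per_plane(1L), col = per_plane(2L), slice = per_plane(3L),
    max3d = max3d)
}

#' The 14 shape features of a mask
#'
#' Computes the full shape-feature set: elongation, flatness, least / major /
#' minor principal-axis lengths, maximum 2D diameters per orthogonal plane
#' family, maximum 3D diameter (largest pairwise boundary-voxel distance),
#' mesh and voxel-counting volume, sphericity
#' `(36 pi V^2)^(1/3) / A` (mesh V, A), surface area and surface/volume
#' ratio.
#'
#' @inheritParams principal_axes
#' @return Named numeric vector of length 14 (see [shape_feature_names()]).
#' @export
shape_features <- function(mask, spacing_mm = NULL) {
  b <- as_binary_mask(mask, spacing_mm)
  if (!any(b$m)) stopf("degenerate mask: empty (all features undefined)")
  pa <- principal_axes(b$m, b$sp)
  ms <- mesh_surface(b$m, b$sp)
  dm <- max_diameters(b$m, b$sp)
  vox_vol <- sum(b$m) * prod(b$sp)
  sph <- (36 * pi * ms$mesh_volume_mm3^2)^(1 / 3) / ms$surface_area_mm2
  setNames(c(pa$elongation, pa$flatness, pa$lengths_mm[3], pa$lengths_mm[1],
             pa$lengths_mm[2], dm[["row"]], dm[["col"]], dm[["slice"]],
             dm[["max3d"]], ms$mesh_volume_mm3, vox_vol, sph,
             ms$surface_area_mm2,
             ms$surface_area_mm2 / ms$mesh_volume_mm3),
           shape_feature_names())
}

#' The 56-dimensional shape feature vector of an organ mask
#'
#' 14 shape features for each of uterus, bladder, rectum and ovary (left and
#' right ovary merged into one structure before extraction), concatenated in
#' that fixed organ order with names `organ__feature`. An absent organ
#' yields `NA` features and is listed in the `missing_organs` attribute
#' (downstream classifiers impute training-set medians).
#'
#' @param organ_mask a `pv_label_mask` carrying the organ label table.
#' @return Named numeric vector of length 56.
#' @export
feature_vector <- function(organ_mask) {
  stopifnot(inherits(organ_mask, "pv_label_mask"))
  organs <- c("uterus", "bladder", "rectum", "ovary")
  sp <- organ_mask$spacing_mm
  missing <- character(0)
  out <- lapply(organs, function(org) {
    m <- if (org == "ovary")
      mask_of(organ_mask, "ovary_left") | mask_of(organ_mask, "ovary_right")
    else mask_of(organ_mask, org)
    f <- tryCatch(shape_features(m, sp), error = function(e) NULL)
    if (is.null(f)) {
      missing <<- c(missing, org)
      f <- setNames(rep(NA_real_, 14), shape_feature_names())
    }
    setNames(f, paste0(org, "__", names(f)))
  })
  structure(unlist(out), missing_organs = missing)
}
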