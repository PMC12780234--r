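#' Severity category from plaque depth
#'
#' The clinical grading rule: none (zero mm), mild (under 5 mm), severe
#' (5 mm or more). The 5 mm boundary belongs to "severe".
#'
#' @param depth_mm nonnegative depth in mm (NA treated as absent).
#' @return One of `"none"`, `"mild"`, `"severe"`.
#' @export
severity_from_depth <- function(depth_mm) {
  vapply(depth_mm, function(d) {
    if (is.na(d) || d == 0) "none" else if (d < 5) "mild" else "severe"
  }, character(1))
}

#' Per-slice plaque depth by the supporting-line construction
#'
#' Implements the slice-wise depth measurement: (1) the plaque contour
#' points lying within `contact_dist_mm` of the uterus boundary form the
#' contact set; (2) the line spanning the contact set -- its principal
#' direction, which for a clean contour is the chord through the two extreme
#' contact points, but is robust to the raster staircase -- gives the
#' direction of the posterior surface; (3) translating that line's intercept
#' gives the two parallel supporting lines enclosing every plaque pixel;
#' (4) depth is their perpendicular separation in mm (one pixel width is
#' added for the pixels' own footprint).
#'
#' @param uterus2d,plaque2d logical matrices on the same pixel grid.
#' @param spacing2d in-plane pixel spacing (mm pair).
#' @param contact_dist_mm contact search distance (default 0.9 mm = 1.5
#'   in-plane voxels of the working grid, one pixel row of contact).
#' @return Depth in mm, or `NA` (with a `"reason"` attribute) when the
#'   plaque is empty or no contact set of at least two points exists.
#' @export
plaque_depth_slice <- function(uterus2d, plaque2d, spacing2d = c(0.6, 0.6),
                               contact_dist_mm = 0.9) {
  stopifnot(is.matrix(uterus2d), is.matrix(plaque2d),
            all(dim(uterus2d) == dim(plaque2d)))
  if (contact_dist_mm <= 0) stopf("`contact_dist_mm` must be > 0")
  if (!any(plaque2d))
    return(structure(NA_real_, reason = "empty plaque"))
  px_mm <- function(idx) cbind((idx[, 1] - 1) * spacing2d[1],
                               (idx[, 2] - 1) * spacing2d[2])
  pc <- px_mm(which(contour_pixels(plaque2d), arr.ind = TRUE))
  ub <- px_mm(which(contour_pixels(uterus2d), arr.ind = TRUE))
  if (nrow(ub) == 0)
    return(structure(NA_real_, reason = "no uterus boundary"))
  # nearest uterus-boundary distance for each plaque contour point
  d2 <- outer(pc[, 1], ub[, 1], "-")^2 + outer(pc[, 2], ub[, 2], "-")^2
  near <- sqrt(apply(d2, 1, min)) <= contact_dist_mm
  contact <- pc[near, , drop = FALSE]
  contact <- unique(contact)
  if (nrow(contact) < 2)
    return(structure(NA_real_, reason = "contact set has < 2 points"))
  if (nrow(contact) == 2) {
    dvec <- contact[2, ] - contact[1, ]
  } else {
    # principal direction of the contact set; equals the extreme-point chord
    # for a clean contour but resists single-pixel staircase jitter
    cc <- sweep(contact, 2, colMeans(contact))
    dvec <- eigen(crossprod(cc), symmetric = TRUE)$vectors[, 1]
  }
  dvec <- dvec / sqrt(sum(dvec^2))
  nvec <- c(-dvec[2], dvec[1])
  # supporting lines through pixel centers, plus one pixel width for the
  # pixels' own footprint (keeps the measure rotation-stable)
  ctr <- px_mm(which(plaque2d, arr.ind = TRUE))
  proj <- ctr[, 1] * nvec[1] + ctr[, 2] * nvec[2]
  structure(max(proj) - min(proj) + mean(spacing2d), direction = dvec)
}

#' Plaque depth, width and severity from an organ label mask
#'
#' Computes the supporting-line depth on every through-plane slice and
#' reports the maximum across slices, the slice attaining it, the in-slice
#' width (extent parallel to the bounding lines on the argmax slice) and the
#' severity category (none / mild < 5 mm / severe >= 5 mm).
#'
#' @param organ_mask a `pv_label_mask` carrying at least a `uterus` label;
#'   the `plaque` label may be empty.
#' @param contact_dist_mm contact search distance; `NULL` (default) uses
#'   1.5 in-plane voxels, which scales with the grid.
#' @return A list of class `pv_plaque_measurement` with `depth_mm`,
#'   `argmax_slice`, `width_mm`, `severity`.
#' @export
plaque_depth <- function(organ_mask, contact_dist_mm = NULL) {
  stopifnot(inherits(organ_mask, "pv_label_mask"))
  contact_dist_mm <- contact_dist_mm %||% (1.5 * organ_mask$spacing_mm[1])
  if (!"uterus" %in% names(organ_mask$labels %||% c()))
    stopf("organ mask has no 'uterus' label")
  ut <- mask_of(organ_mask, "uterus")
  pl <- if ("plaque" %in% names(organ_mask$labels)) mask_of(organ_mask, "plaque")
        else array(FALSE, dim(organ_mask$data))
  sp <- organ_mask$spacing_mm
  nz <- dim(ut)[3]
  depths <- rep(NA_real_, nz)
  dirs <- vector("list", nz)
  for (k in seq_len(nz)) {
    if (!any(pl[, , k])) next
    d <- plaque_depth_slice(ut[, , k], pl[, , k], sp[1:2], contact_dist_mm)
    depths[k] <- as.double(d)
    dirs[[k]] <- attr(d, "direction")
  }
  if (all(is.na(depths))) {
    out <- list(depth_mm = 0, argmax_slice = NA_integer_, width_mm = 0,
                severity = "none")
    class(out) <- "pv_plaque_measurement"
    return(out)
  }
  k <- which.max(depths)
  dvec <- dirs[[k]]
  idx <- which(pl[, , k], arr.ind = TRUE)
  ctr <- cbind((idx[, 1] - 1) * sp[1], (idx[, 2] - 1) * sp[2])
  proj <- ctr[, 1] * dvec[1] + ctr[, 2] * dvec[2]
  out <- list(depth_mm = max(depths, na.rm = TRUE),
              argmax_slice = k,
              width_mm = max(proj) - min(proj) + mean(sp[1:2]),
              severity = severity_from_depth(max(depths, na.rm = TRUE)))
  class(out) <- "pv_plaque_measurement"
  out
}

#' @export
print.pv_plaque_measurement <- function(x, ...) {
  cat(sprintf("<plaque> depth %.2f mm (%s), width %.2f mm, slice %s\n",
              x$depth_mm, x$severity, x$width_mm, x$argmax_slice))
  invisible(x)
}

# direct least-squares ellipse fit (Fitzgibbon-style conic with the
# 4ac - b^2 = 1 constraint) to points in mm; returns center, semi-axes, angle
fit_conic_ellipse <- function(pts) {
  x <- pts[, 1] - mean(pts[, 1])
  y <- pts[, 2] - mean(pts[, 2])
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) -
    Re(ev$vectors[2, ])^2
  ok <- which(cond > 0)
  if (length(ok) == 0) stopf("degenerate contour: ellipse fit failed")
  a1 <- Re(ev$vectors[, ok[1]])
  par <- c(a1, Tm %*% a1) # A B C D E F on centered coords
  A <- par[1]; B <- par[2]; C <- par[3]; D <- par[4]; E <- par[5]; F <- par[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stopf("degenerate contour: not an ellipse")
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + (B^2 - 4 * A * C) * F)
  tmp <- sqrt((A - C)^2 + B^2)
  sa <- suppressWarnings(-sqrt(num * ((A + C) + tmp)) / den)
  sb <- suppressWarnings(-sqrt(num * ((A + C) - tmp)) / den)
  if (!all(is.finite(c(cx, cy, sa, sb))) || sa <= 0 || sb <= 0)
    stopf("degenerate contour: ellipse fit failed")
  ang <- atan2(-B, C - A) / 2
  semi <- sort(c(sa, sb), decreasing = TRUE)
  list(center = c(cx + mean(pts[, 1]), cy + mean(pts[, 2])),
       semi = semi, angle = ang)
}

#' Fit an ellipse to a 2D mask slice and report its axes
#'
#' Direct least-squares conic fit to the 8-connected contour of the region,
#' followed by an area-preserving rescale (the fitted ellipse is scaled so
#' its area equals the pixel-count area of the mask, compensating the
#' half-pixel inward bias of contour-pixel centers).
#'
#' @param mask2d logical matrix (single lesion cross-section).
#' @param spacing2d in-plane spacing, mm pair.
#' @return A list of class `pv_ellipse_axes` with `major_mm`, `minor_mm`,
#'   `center` (mm) and `angle` (radians).
#' @export
fit_ellipse_axes <- function(mask2d, spacing2d = c(0.6, 0.6)) {
  stopifnot(is.matrix(mask2d))
  idx <- which(contour_pixels(mask2d), arr.ind = TRUE)
  if (nrow(idx) < 5)
    stopf("mask contour has fewer than 5 points; cannot fit an ellipse")
  pts <- cbind((idx[, 1] - 1) * spacing2d[1], (idx[, 2] - 1) * spacing2d[2])
  if (qr(sweep(pts, 2, colMeans(pts)))$rank < 2)
    stopf("degenerate (collinear) contour")
  fit <- fit_conic_ellipse(pts)
  pix_area <- sum(mask2d) * prod(spacing2d)
  s <- sqrt(pix_area / (pi * fit$semi[1] * fit$semi[2]))
  out <- list(major_mm = 2 * fit$semi[1] * s,
              minor_mm = 2 * fit$semi[2] * s,
              center = fit$center,
              angle = fit$angle)
  class(out) <- "pv_ellipse_axes"
  out
}

#' Largest-slice ellipse axes of ovarian endometriotic cysts
#'
#' Fits every axial slice of each connected lesion (26-connectivity,
#' components ordered by size descending) to an ellipse and reports, per
#' lesion, the axes of the slice whose fitted ellipse has the largest area.
#'
#' @param oec_mask a `pv_label_mask` of the cyst segmentation.
#' @return List of `pv_ellipse_axes`, one per lesion, each with a
#'   `slice_index` element; single lesion gives a length-1 list.
#' @export
oec_axes <- function(oec_mask) {
  stopifnot(inherits(oec_mask, "pv_label_mask"))
  fg <- oec_mask$data != 0L
  if (!any(fg)) stopf("empty cyst mask")
  d <- dim(fg)
  lab <- array(.cpp_label3d(as.logical(fg), as.integer(d), 26L), d)
  sizes <- tabulate(lab[lab > 0L])
  comp_order <- order(sizes, decreasing = TRUE)
  sp <- oec_mask$spacing_mm
  out <- list()
  for (comp in comp_order) {
    best <- NULL
    for (k in seq_len(d[3])) {
      sl <- lab[, , k] == comp
      if (sum(sl) < 9) next
      fit <- tryCatch(fit_ellipse_axes(sl, sp[1:2]), error = function(e) NULL)
      if (is.null(fit)) next
      area <- pi * fit$major_mm * fit$minor_mm / 4
      if (is.null(best) || area > best$area) {
        fit$slice_index <- k
        fit$area <- area
        best <- fit
      }
    }
    if (!is.null(best)) out[[length(out) + 1L]] <- best
  }
  if (length(out) == 0) stopf("no slice of the cyst mask supports an ellipse fit")
  out
}

#' Voxel-counting volume of a mask
#'
#' Volume approximated by counting foreground voxels times the voxel volume
#' (2.16 mm^3 on the 0.6 x 0.6 x 6.0 mm working grid).
#'
#' @param mask a `pv_label_mask` (all nonzero labels count) or logical array
#'   with a `spacing_mm` argument.
#' @param spacing_mm required when `mask` is a bare array.
#' @return Volume in mm^3.
#' @export
mask_volume <- function(mask, spacing_mm = NULL) {
  if (inherits(mask, "pv_label_mask"))
    return(sum(mask$data != 0L) * prod(mask$spacing_mm))
  if (is.null(spacing_mm)) stopf("`spacing_mm` required for a bare array")
  sum(mask != 0) * prod(spacing_mm)
}

#' Pre/post cyst volume change
#'
#' @param pre_mask,post_mask cyst `pv_label_mask`s.
#' @return List of class `pv_volume_change` with `pre_mm3`, `post_mm3`,
#'   `delta_mm3` (= post - pre).
#' @export
volume_change <- function(pre_mask, post_mask) {
  pre <- mask_volume(pre_mask)
  post <- mask_volume(post_mask)
  structure(list(pre_mm3 = pre, post_mm3 = post, delta_mm3 = post - pre),
            class = "pv_volume_change")
}
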