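#' The seven pelvic adhesion locations
#'
#' Fixed-order location set used everywhere adhesions are labelled,
#' classified or reported: left ovary-rectum, right ovary-rectum, left-right
#' ovary, uterus-left ovary, uterus-right ovary, uterus-rectum,
#' uterus-bladder.
#'
#' @return Character vector of length 7.
#' @export
adhesion_locations <- function() {
  c("left_ovary-rectum", "right_ovary-rectum", "left-right_ovary",
    "uterus-left_ovary", "uterus-right_ovary", "uterus-rectum",
    "uterus-bladder")
}

# organ pair and which member(s) translate toward the other
location_pairs <- function() {
  list(
    "left_ovary-rectum"  = list(pair = c("ovary_left", "rectum"),  move = "ovary_left"),
    "right_ovary-rectum" = list(pair = c("ovary_right", "rectum"), move = "ovary_right"),
    "left-right_ovary"   = list(pair = c("ovary_left", "ovary_right"), move = "both"),
    "uterus-left_ovary"  = list(pair = c("uterus", "ovary_left"),  move = "ovary_left"),
    "uterus-right_ovary" = list(pair = c("uterus", "ovary_right"), move = "ovary_right"),
    "uterus-rectum"      = list(pair = c("uterus", "rectum"),      move = "rectum"),
    "uterus-bladder"     = list(pair = c("uterus", "bladder"),     move = "bladder"))
}

#' Organ label codes used by phantom masks
#' @return Named integer vector.
#' @export
organ_labels <- function() {
  c(uterus = 1L, bladder = 2L, rectum = 3L, ovary_left = 4L,
    ovary_right = 5L, plaque = 6L)
}

#' Phantom specification
#'
#' Describes one synthetic pelvic sample: grid, plaque depth, optional
#' ovarian endometriotic cyst (OEC) axes, per-location adhesion flags and
#' intensity noise. All downstream ground truth is analytic in these
#' parameters.
#'
#' @param image_shape voxels per axis (default `c(192, 192, 20)`).
#' @param spacing_mm voxel spacing, default `c(0.6, 0.6, 6.0)` mm (the
#'   working grid of the pipeline).
#' @param plaque_depth_mm target maximal outward plaque extent, >= 0
#'   (0 = no plaque).
#' @param oec_axes_mm `c(major, minor)` in-plane cyst axes in mm, or `NULL`
#'   for no cyst.
#' @param oec_through_mm through-plane cyst semi-axis, mm.
#' @param adhesion_flags logical vector of length 7 named as
#'   [adhesion_locations()].
#' @param noise_sd Gaussian intensity noise SD (tissue levels live on a
#'   0-1 scale).
#' @param seed optional integer controlling per-sample anatomical jitter.
#' @return A list of class `pv_phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(192, 192, 20),
                         spacing_mm = c(0.6, 0.6, 6.0),
                         plaque_depth_mm = 0,
                         oec_axes_mm = NULL,
                         oec_through_mm = 16,
                         adhesion_flags = setNames(rep(FALSE, 7),
                                                   adhesion_locations()),
                         noise_sd = 0.05,
                         seed = NULL) {
  check_length3(spacing_mm, "`spacing_mm`")
  if (any(spacing_mm <= 0)) stopf("`spacing_mm` must be strictly positive")
  if (plaque_depth_mm < 0) stopf("`plaque_depth_mm` must be >= 0")
  if (!is.null(oec_axes_mm)) {
    if (length(oec_axes_mm) != 2L || oec_axes_mm[1] < oec_axes_mm[2] ||
        oec_axes_mm[2] <= 0)
      stopf("`oec_axes_mm` must be (major, minor) with major >= minor > 0")
  }
  if (length(adhesion_flags) != 7L)
    stopf("`adhesion_flags` must have length 7")
  flags <- setNames(as.logical(adhesion_flags), adhesion_locations())
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  structure(list(image_shape = as.integer(image_shape),
                 spacing_mm = as.double(spacing_mm),
                 plaque_depth_mm = as.double(plaque_depth_mm),
                 oec_axes_mm = if (is.null(oec_axes_mm)) NULL else as.double(oec_axes_mm),
                 oec_through_mm = as.double(oec_through_mm),
                 adhesion_flags = flags,
                 noise_sd = as.double(noise_sd),
                 seed = seed),
            class = "pv_phantom_spec")
}

# Base anatomy: axis-aligned ellipsoids, sizes in mm, centers as fractions of
# the field of view (defaults reproduce the mm placements documented in the
# methods vignette at the default 115.2 x 115.2 x 120 mm FOV). Axis 1 is
# anterior-posterior, axis 2 superior-inferior (both in-plane on the sagittal
# T2 stack), axis 3 left-right (through-plane).
base_anatomy <- function(fov) {
  mk <- function(cf, semi) list(center = cf * fov, semi = semi,
                                M = diag(1 / semi^2), cuts = list())
  list(
    uterus      = mk(c(0.5208, 0.5000, 0.50), c(15, 22, 14)),
    bladder     = mk(c(0.2431, 0.5000, 0.50), c(13, 17, 12)),
    rectum      = mk(c(0.8420, 0.6200, 0.50), c(8, 24, 9)),
    ovary_left  = mk(c(0.7300, 0.5000, 0.70), c(9, 11, 8)),
    ovary_right = mk(c(0.7300, 0.5000, 0.30), c(9, 11, 8)))
}

tissue_levels <- function() {
  c(background = 0.10, uterus = 0.60, bladder = 0.90, rectum = 0.45,
    ovary_left = 0.70, ovary_right = 0.70, plaque = 0.35,
    t1_background = 0.15, oec = 0.85)
}

# support radius of {x : x' M x <= 1} along unit direction u
support_radius <- function(M, u) sqrt(drop(t(u) %*% solve(M, u)))

# stretch the quadric by factor f along u and g perpendicular to u
stretch_quadric <- function(M, u, f, g) {
  P <- tcrossprod(u)
  Tinv <- (1 / f) * P + (1 / g) * (diag(3) - P)
  Tinv %*% M %*% Tinv
}

# rasterize one organ over voxel-center coordinates X (n x 3)
rasterize_organ <- function(X, organ) {
  Y <- sweep(X, 2, organ$center)
  q <- rowSums((Y %*% organ$M) * Y)
  inside <- q <= 1
  for (cut in organ$cuts)
    inside <- inside & (Y %*% cut$normal - sum(cut$normal * (cut$point - organ$center)) <= 0)
  inside
}

# paint an organ's label code into the flat label vector, evaluating the
# quadric only on the organ's bounding subgrid (keeps cohort generation fast)
paint_organ <- function(lab, d, sp, organ, code) {
  r <- sqrt(pmax(diag(solve(organ$M)), 0))
  ilo <- pmax(1L, as.integer(floor((organ$center - r) / sp)) )
  ihi <- pmin(d, as.integer(ceiling((organ$center + r) / sp)) + 2L)
  if (any(ihi < ilo)) return(lab)
  xi <- ilo[1]:ihi[1]; yi <- ilo[2]:ihi[2]; zi <- ilo[3]:ihi[3]
  nx <- length(xi); ny <- length(yi); nz <- length(zi)
  X <- cbind(rep((xi - 1) * sp[1], times = ny * nz),
             rep(rep((yi - 1) * sp[2], each = nx), times = nz),
             rep((zi - 1) * sp[3], each = nx * ny))
  inside <- rasterize_organ(X, organ)
  li <- (rep(zi, each = nx * ny) - 1L) * (d[1] * d[2]) +
    (rep(rep(yi, each = nx), times = nz) - 1L) * d[1] +
    rep(xi, times = ny * nz)
  li <- li[inside & lab[li] == 0L]
  lab[li] <- code
  lab
}

apply_adhesions <- function(organs, flags,
                            stretch = 1.35, perp = 0.95, cap_mm = 1.5,
                            residual_gap_mm = 0.5) {
  for (loc in adhesion_locations()) {
    if (!isTRUE(flags[[loc]])) next
    info <- location_pairs()[[loc]]
    a <- info$pair[1]; b <- info$pair[2]
    u <- organs[[b]]$center - organs[[a]]$center
    u <- u / sqrt(sum(u^2))
    organs[[a]]$M <- stretch_quadric(organs[[a]]$M, u, stretch, perp)
    organs[[b]]$M <- stretch_quadric(organs[[b]]$M, u, stretch, perp)
    ha <- support_radius(organs[[a]]$M, u)
    hb <- support_radius(organs[[b]]$M, u)
    organs[[a]]$cuts <- c(organs[[a]]$cuts, list(list(
      point = organs[[a]]$center + (ha - cap_mm) * u, normal = u)))
    organs[[b]]$cuts <- c(organs[[b]]$cuts, list(list(
      point = organs[[b]]$center - (hb - cap_mm) * u, normal = -u)))
    gap <- sqrt(sum((organs[[b]]$center - organs[[a]]$center)^2)) -
      (ha - cap_mm) - (hb - cap_mm)
    shift <- max(gap - residual_gap_mm, 0)
    if (identical(info$move, "both")) {
      organs[[a]]$center <- organs[[a]]$center + (shift / 2) * u
      organs[[b]]$center <- organs[[b]]$center - (shift / 2) * u
    } else if (identical(info$move, a)) {
      organs[[a]]$center <- organs[[a]]$center + shift * u
    } else {
      organs[[b]]$center <- organs[[b]]$center - shift * u
    }
  }
  organs
}

#' Generate one synthetic pelvic phantom
#'
#' Builds paired T2 (sagittal-convention) and T1 (axial-convention) volumes
#' plus organ and cyst label masks whose ground-truth plaque depth, cyst axes
#' and cyst volume are known analytically. The plaque is a slab of constant
#' thickness grown posteriorly from a flattened facet of the posterior
#' uterine surface, so its maximal outward extent equals
#' `spec$plaque_depth_mm` exactly; flagged adhesions pull the named organ
#' pair into near contact, flatten the apposed surfaces, and elongate both
#' organs (reducing sphericity).
#'
#' @param spec a [phantom_spec()].
#' @return A `pv_phantom_sample`: list with `t2_volume`, `t1_volume`,
#'   `organ_mask`, `oec_mask`, `truth` and `patient_id`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "pv_phantom_spec"))
  with_seed(spec$seed, function() generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  d <- spec$image_shape
  sp <- spec$spacing_mm
  fov <- d * sp
  lv <- tissue_levels()
  organs <- base_anatomy(fov)
  # per-sample anatomical jitter (axes +-5%, centers ~1 mm in-plane)
  for (nm in names(organs)) {
    organs[[nm]]$semi <- organs[[nm]]$semi * exp(rnorm(3, 0, 0.05))
    organs[[nm]]$M <- diag(1 / organs[[nm]]$semi^2)
    organs[[nm]]$center <- organs[[nm]]$center +
      c(rnorm(2, 0, 1.0), rnorm(1, 0, 0.5))
  }
  # posterior uterine facet: plane cut 3 mm anterior of the posterior pole,
  # snapped to a voxel footprint boundary along axis 1
  ut <- organs$uterus
  facet_x <- ut$center[1] + support_radius(ut$M, c(1, 0, 0)) - 3
  facet_x <- (round(facet_x / sp[1] - 0.5) + 0.5) * sp[1]
  has_plaque <- spec$plaque_depth_mm > 0
  if (has_plaque)
    organs$uterus$cuts <- c(organs$uterus$cuts, list(list(
      point = c(facet_x, 0, 0), normal = c(1, 0, 0))))
  organs <- apply_adhesions(organs, spec$adhesion_flags)

  # containment check: support extents must stay inside the grid
  for (nm in names(organs)) {
    o <- organs[[nm]]
    for (ax in 1:3) {
      e <- rep(0, 3); e[ax] <- 1
      r <- support_radius(o$M, e)
      if (o$center[ax] - r < 0 || o$center[ax] + r > fov[ax])
        stopf("phantom spec rejected: organ '%s' would clip the %.0f mm FOV along axis %d",
              nm, fov[ax], ax)
    }
  }

  nvox <- prod(d)
  lab <- integer(nvox)
  codes <- organ_labels()
  for (nm in c("uterus", "bladder", "ovary_left", "ovary_right", "rectum"))
    lab <- paint_organ(lab, d, sp, organs[[nm]], codes[[nm]])

  depth <- spec$plaque_depth_mm
  n_rows_expected <- if (has_plaque) as.integer(ceiling(depth / sp[1] - 1e-9)) else 0L
  if (has_plaque) {
    yc <- organs$uterus$center[2]
    zc <- organs$uterus$center[3]
    # any-coverage rasterization along the facet normal: a voxel row belongs
    # to the slab when its footprint intersects (facet, facet + depth]
    i_first <- as.integer(round(facet_x / sp[1] - 0.5)) + 2L # 1-based row after the facet
    rows <- i_first:(i_first + n_rows_expected - 1L)
    rows <- rows[rows >= 1L & rows <= d[1]]
    ycols <- which(abs(axis_coords(d[2], sp[2]) - yc) <= 8)
    zsls <- which(abs(axis_coords(d[3], sp[3]) - zc) <= 6)
    li <- as.vector(outer(outer(rows, (ycols - 1L) * d[1], "+"),
                          (zsls - 1L) * (d[1] * d[2]), "+"))
    li <- li[lab[li] != codes[["uterus"]]]
    lab[li] <- codes[["plaque"]]
    got_rows <- length(unique((li - 1L) %% d[1]))
    if (got_rows != length(rows) || length(rows) != n_rows_expected)
      stopf("phantom spec rejected: organs overlap inconsistently (plaque slab truncated: %d of %d rows rasterized)",
            got_rows, n_rows_expected)
    # the slab must actually abut the uterine facet
    i_facet <- i_first - 1L
    fb <- as.vector(outer(outer(i_facet, (ycols - 1L) * d[1], "+"),
                          (zsls - 1L) * (d[1] * d[2]), "+"))
    if (!any(lab[fb] == codes[["uterus"]]))
      stopf("phantom spec rejected: plaque slab does not contact the uterine facet")
  }

  intens <- rep(lv[["background"]], nvox)
  for (nm in c("uterus", "bladder", "rectum", "ovary_left", "ovary_right",
               "plaque"))
    intens[lab == codes[[nm]]] <- lv[[nm]]
  if (spec$noise_sd > 0)
    intens <- intens + rnorm(length(intens), 0, spec$noise_sd)

  organ_mask <- label_mask(array(lab, d), sp, labels = codes)
  t2 <- volume(array(intens, d), sp)

  # T1 grid: same shape/spacing; OEC ellipsoid centered mid-FOV with its
  # center snapped to a slice center so the largest-area slice is exact
  oec_lab <- integer(nvox)
  truth_axes <- NULL
  if (!is.null(spec$oec_axes_mm)) {
    a2 <- spec$oec_axes_mm[1] / 2
    b2 <- spec$oec_axes_mm[2] / 2
    c2 <- spec$oec_through_mm
    theta <- runif(1, 0, pi)
    R <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0),
               c(0, 0, 1))
    M <- R %*% diag(1 / c(a2, b2, c2)^2) %*% t(R)
    ctr <- fov / 2
    ctr[3] <- round(ctr[3] / sp[3]) * sp[3]
    for (ax in 1:3) {
      e <- rep(0, 3); e[ax] <- 1
      r <- support_radius(M, e)
      if (ctr[ax] - r < 0 || ctr[ax] + r > fov[ax])
        stopf("phantom spec rejected: OEC would clip the FOV along axis %d", ax)
    }
    oec_lab <- paint_organ(oec_lab, d, sp,
                           list(center = ctr, M = M, cuts = list()), 1L)
    truth_axes <- spec$oec_axes_mm
  }
  t1_int <- rep(lv[["t1_background"]], nvox)
  t1_int[oec_lab == 1L] <- lv[["oec"]]
  if (spec$noise_sd > 0)
    t1_int <- t1_int + rnorm(length(t1_int), 0, spec$noise_sd)
  oec_mask <- label_mask(array(oec_lab, d), sp, labels = c(oec = 1L))
  t1 <- volume(array(t1_int, d), sp)

  truth <- list(
    plaque_depth_mm = depth,
    severity = severity_from_depth(depth),
    oec_axes_mm = truth_axes,
    oec_volume_mm3 = sum(oec_lab == 1L) * prod(sp),
    adhesion = spec$adhesion_flags)

  structure(list(t2_volume = t2, t1_volume = t1, organ_mask = organ_mask,
                 oec_mask = oec_mask, truth = truth, patient_id = "P000"),
            class = "pv_phantom_sample")
}

#' @export
print.pv_phantom_sample <- function(x, ...) {
  cat(sprintf("<pv_phantom_sample> %s, depth %.2f mm (%s), OEC %s, adhesions: %s\n",
              x$patient_id, x$truth$plaque_depth_mm, x$truth$severity,
              if (is.null(x$truth$oec_axes_mm)) "absent"
              else paste(format(x$truth$oec_axes_mm), collapse = "x"),
              paste(names(which(x$truth$adhesion)), collapse = ", ")))
  invisible(x)
}

# shrink the cyst of a spec by a volume factor (axes scale by factor^(1/3))
shrink_oec_spec <- function(spec, factor) {
  stopifnot(inherits(spec, "pv_phantom_spec"), factor > 0, factor <= 1,
            !is.null(spec$oec_axes_mm))
  s <- factor^(1 / 3)
  spec$oec_axes_mm <- spec$oec_axes_mm * s
  spec$oec_through_mm <- spec$oec_through_mm * s
  spec
}

#' Generate a reproducible phantom cohort
#'
#' Draws per-patient adhesion labels Bernoulli(prevalence) per location,
#' plaque depths (a point mass at zero plus a uniform range) and optional
#' OECs; a fraction of cyst-bearing patients contribute a pre/post pair in
#' which the cyst volume shrinks by a random factor in `[0.1, 0.9]`,
#' exercising the volume-change pipeline.
#'
#' @param n number of samples (images) to generate.
#' @param seed integer; fixed seed gives a bit-identical cohort.
#' @param prevalence 7 adhesion prevalences in `[0, 1]` ordered as
#'   [adhesion_locations()]; defaults follow the positive-sample rates of the
#'   study population (38, 37, 16, 73, 66, 62 and 6 percent).
#' @param image_shape,spacing_mm,noise_sd forwarded to [phantom_spec()].
#' @param depth_range plaque depth range (mm) for plaque-bearing samples.
#' @param p_no_plaque probability of a plaque-free (severity "none") sample.
#' @param p_oec probability a patient carries a cyst.
#' @param pair_fraction fraction of cyst-bearing patients contributing a
#'   pre/post pair.
#' @return List of `pv_phantom_sample`.
#' @export
generate_cohort <- function(n, seed = 1,
                            prevalence = c(0.38, 0.37, 0.16, 0.73, 0.66,
                                           0.62, 0.06),
                            image_shape = c(192, 192, 20),
                            spacing_mm = c(0.6, 0.6, 6.0),
                            noise_sd = 0.05,
                            depth_range = c(0, 12),
                            p_no_plaque = 0.25,
                            p_oec = 0.6,
                            pair_fraction = 0.2) {
  if (n < 1) stopf("`n` must be >= 1")
  if (length(prevalence) != 7L || any(prevalence < 0 | prevalence > 1))
    stopf("`prevalence` must be 7 values in [0, 1]")
  with_seed(seed, function() {
    samples <- vector("list", n)
    i <- 1L
    patient <- 0L
    while (i <= n) {
      patient <- patient + 1L
      pid <- sprintf("P%03d", patient)
      flags <- setNames(runif(7) < prevalence, adhesion_locations())
      depth <- if (runif(1) < p_no_plaque) 0
               else runif(1, depth_range[1], depth_range[2])
      oec <- NULL
      if (runif(1) < p_oec) {
        minor <- runif(1, 18, 32)
        oec <- c(minor * runif(1, 1.1, 1.7), minor)
      }
      sub_seed <- sample.int(.Machine$integer.max, 1)
      spec <- phantom_spec(image_shape = image_shape, spacing_mm = spacing_mm,
                           plaque_depth_mm = depth, oec_axes_mm = oec,
                           adhesion_flags = flags, noise_sd = noise_sd,
                           seed = sub_seed)
      s <- generate_phantom(spec)
      s$patient_id <- pid
      s$image_id <- sprintf("%s_pre", pid)
      samples[[i]] <- s
      i <- i + 1L
      if (!is.null(oec) && i <= n && runif(1) < pair_fraction) {
        post_spec <- shrink_oec_spec(spec, runif(1, 0.1, 0.9))
        post_spec$seed <- sample.int(.Machine$integer.max, 1)
        s2 <- generate_phantom(post_spec)
        s2$patient_id <- pid
        s2$image_id <- sprintf("%s_post", pid)
        samples[[i]] <- s2
        i <- i + 1L
      }
    }
    samples
  })
}
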