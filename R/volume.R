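#' 3D image volume
#'
#' Lightweight container for a 3D scalar image with per-axis voxel spacing in
#' mm. Axis convention: axis 1 = in-plane rows, axis 2 = in-plane columns,
#' axis 3 = slice (through-plane) direction. Voxel indices are 0-based in
#' world-coordinate formulas: `world = index * spacing + origin`.
#'
#' @param data 3D numeric array.
#' @param spacing_mm positive numeric triple, voxel spacing in mm
#'   (default `c(0.6, 0.6, 6.0)`, the working grid all inputs are resampled
#'   to).
#' @param origin world-coordinate (mm) of the first voxel's center.
#' @return An object of class `pv_volume`.
#' @export
volume <- function(data, spacing_mm = c(0.6, 0.6, 6.0), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a 3D array")
  check_length3(spacing_mm, "`spacing_mm`")
  check_length3(origin, "`origin`")
  if (any(spacing_mm <= 0)) stopf("`spacing_mm` must be strictly positive")
  if (any(!is.finite(data))) stopf("volume data must be finite")
  structure(list(data = data, spacing_mm = as.double(spacing_mm),
                 origin = as.double(origin)),
            class = "pv_volume")
}

#' @export
print.pv_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing_mm), collapse = " x ")))
  invisible(x)
}

#' Integer label mask aligned to a volume
#'
#' @param data 3D integer array of label codes (0 = background).
#' @param spacing_mm,origin as in [volume()].
#' @param labels named integer vector mapping structure names to codes,
#'   e.g. `c(uterus = 1, plaque = 6)`.
#' @return An object of class `pv_label_mask` (also a `pv_volume`).
#' @export
label_mask <- function(data, spacing_mm = c(0.6, 0.6, 6.0),
                       origin = c(0, 0, 0), labels = NULL) {
  storage.mode(data) <- "integer"
  v <- volume(data, spacing_mm, origin)
  if (!is.null(labels)) {
    if (is.null(names(labels)) || any(names(labels) == ""))
      stopf("`labels` must be a named integer vector")
    v$labels <- setNames(as.integer(labels), names(labels))
  }
  class(v) <- c("pv_label_mask", "pv_volume")
  v
}

# binary array for one named label (or all foreground when label is NULL)
mask_of <- function(m, label = NULL) {
  stopifnot(inherits(m, "pv_label_mask"))
  if (is.null(label)) return(m$data != 0L)
  if (!label %in% names(m$labels %||% c()))
    stopf("label '%s' not present in mask label table", label)
  m$data == m$labels[[label]]
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti preserving spacing (and the affine on write as a
#' diagonal scaling). Masks round-trip as integer arrays.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a `pv_volume`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  volume(array(as.double(img), dim = dim(img)[1:3]), spacing_mm = sp)
}

#' @param v a `pv_volume` (or `pv_label_mask`).
#' @rdname read_volume
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "pv_volume"))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Z-score intensity normalization
#'
#' Subtracts the volume mean and divides by the standard deviation, the
#' standard intensity preprocessing applied to every input volume.
#'
#' @param v a `pv_volume` with at least two distinct values.
#' @return Normalized `pv_volume` (mean 0, SD 1).
#' @export
znormalize <- function(v) {
  stopifnot(inherits(v, "pv_volume"))
  s <- sd(v$data)
  if (!is.finite(s) || s == 0)
    stopf("cannot z-normalize a constant volume (zero variance)")
  volume((v$data - mean(v$data)) / s, v$spacing_mm, v$origin)
}

#' Resample a volume to a target voxel spacing
#'
#' Preserves the physical extent; intensities are interpolated trilinearly,
#' label masks with nearest-neighbour. The working grid used throughout is
#' 0.6 x 0.6 x 6.0 mm.
#'
#' @param v a `pv_volume` or `pv_label_mask`.
#' @param target_spacing positive mm triple.
#' @return Resampled object of the same class.
#' @export
resample <- function(v, target_spacing = c(0.6, 0.6, 6.0)) {
  stopifnot(inherits(v, "pv_volume"))
  check_length3(target_spacing, "`target_spacing`")
  if (any(target_spacing <= 0)) stopf("`target_spacing` must be positive")
  d <- dim(v$data)
  if (isTRUE(all.equal(v$spacing_mm, as.double(target_spacing))))
    return(v)
  extent <- d * v$spacing_mm
  nd <- pmax(1L, as.integer(round(extent / target_spacing)))
  is_mask <- inherits(v, "pv_label_mask")
  # cell-centered alignment over the shared physical extent:
  # source center i at (i + 0.5) * s, target center j at (j + 0.5) * t
  src_pos <- lapply(1:3, function(ax)
    ((seq_len(nd[ax]) - 0.5) * target_spacing[ax]) / v$spacing_mm[ax] - 0.5)
  if (is_mask) {
    idx <- lapply(1:3, function(ax)
      pmin(pmax(as.integer(round(src_pos[[ax]])), 0L), d[ax] - 1L) + 1L)
    out <- v$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    res <- label_mask(array(out, nd), target_spacing, v$origin,
                      labels = v$labels)
    return(res)
  }
  lo <- lapply(1:3, function(ax)
    pmin(pmax(floor(src_pos[[ax]]), 0), d[ax] - 1))
  fr <- lapply(1:3, function(ax) {
    f <- src_pos[[ax]] - lo[[ax]]
    pmin(pmax(f, 0), 1)
  })
  hi <- lapply(1:3, function(ax) pmin(lo[[ax]] + 1, d[ax] - 1))
  g <- function(ix, iy, iz) v$data[cbind(
    rep(ix + 1, times = nd[2] * nd[3]),
    rep(rep(iy + 1, each = nd[1]), times = nd[3]),
    rep(iz + 1, each = nd[1] * nd[2]))]
  fx <- rep(fr[[1]], times = nd[2] * nd[3])
  fy <- rep(rep(fr[[2]], each = nd[1]), times = nd[3])
  fz <- rep(fr[[3]], each = nd[1] * nd[2])
  out <-
    g(lo[[1]], lo[[2]], lo[[3]]) * (1 - fx) * (1 - fy) * (1 - fz) +
    g(hi[[1]], lo[[2]], lo[[3]]) * fx * (1 - fy) * (1 - fz) +
    g(lo[[1]], hi[[2]], lo[[3]]) * (1 - fx) * fy * (1 - fz) +
    g(hi[[1]], hi[[2]], lo[[3]]) * fx * fy * (1 - fz) +
    g(lo[[1]], lo[[2]], hi[[3]]) * (1 - fx) * (1 - fy) * fz +
    g(hi[[1]], lo[[2]], hi[[3]]) * fx * (1 - fy) * fz +
    g(lo[[1]], hi[[2]], hi[[3]]) * (1 - fx) * fy * fz +
    g(hi[[1]], hi[[2]], hi[[3]]) * fx * fy * fz
  volume(array(out, nd), target_spacing, v$origin)
}

#' Training-time augmentation parameters
#'
#' Defaults follow the study's training pipeline: random zoom in (0.9, 1.2),
#' a random monotone nonlinear warp of the intensity histogram, an additive
#' intensity offset drawn from (-0.1, 0.1) of the image SD, and Gaussian
#' noise N(0, 0.1).
#'
#' @param zoom_range length-2 numeric, low <= high.
#' @param intensity_shift_range length-2 numeric, in units of the image SD.
#' @param noise_sd nonnegative Gaussian noise SD.
#' @param histogram_warp_strength warp amount in `[0, 1]`; 0 disables the
#'   warp, 1 is a fully random monotone map.
#' @param seed optional integer for reproducible draws.
#' @return A list of class `pv_augmentation_params`.
#' @export
augmentation_params <- function(zoom_range = c(0.9, 1.2),
                                intensity_shift_range = c(-0.1, 0.1),
                                noise_sd = 0.1,
                                histogram_warp_strength = 0.3,
                                seed = NULL) {
  if (length(zoom_range) != 2L || zoom_range[1] > zoom_range[2])
    stopf("`zoom_range` must be (low, high) with low <= high")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  if (histogram_warp_strength < 0 || histogram_warp_strength > 1)
    stopf("`histogram_warp_strength` must be in [0, 1]")
  structure(list(zoom_range = as.double(zoom_range),
                 intensity_shift_range = as.double(intensity_shift_range),
                 noise_sd = as.double(noise_sd),
                 histogram_warp_strength = as.double(histogram_warp_strength),
                 seed = seed),
            class = "pv_augmentation_params")
}

# random monotone piecewise-cubic map of intensities blended with identity
monotone_warp <- function(x, strength) {
  if (strength == 0) return(x)
  rng <- range(x)
  if (rng[1] == rng[2]) return(x)
  u <- (x - rng[1]) / (rng[2] - rng[1])
  knots <- seq(0, 1, length.out = 6)
  incr <- runif(5, 0.2, 1.8)
  y <- c(0, cumsum(incr)) / sum(incr)
  f <- splinefun(knots, (1 - strength) * knots + strength * y,
                 method = "hyman")
  rng[1] + f(u) * (rng[2] - rng[1])
}

#' Apply training augmentation to a volume
#'
#' Order of operations: random zoom (content scaling on a fixed grid),
#' monotone nonlinear intensity warp, additive intensity offset (in units of
#' the image SD), then additive Gaussian noise. Reproducible when the
#' parameter object carries a seed.
#'
#' @param v a (normalized) `pv_volume`.
#' @param p an [augmentation_params()] object.
#' @return Augmented `pv_volume` with the same grid.
#' @export
augment <- function(v, p = augmentation_params()) {
  stopifnot(inherits(v, "pv_volume"), inherits(p, "pv_augmentation_params"))
  with_seed(p$seed, function() {
    d <- dim(v$data)
    z <- runif(1, p$zoom_range[1], p$zoom_range[2])
    out <- v$data
    if (z != 1) {
      ctr <- (d - 1) / 2
      pos <- lapply(1:3, function(ax)
        pmin(pmax(ctr[ax] + ((seq_len(d[ax]) - 1) - ctr[ax]) / z, 0), d[ax] - 1))
      lo <- lapply(pos, floor)
      fr <- lapply(1:3, function(ax) pos[[ax]] - lo[[ax]])
      hi <- lapply(1:3, function(ax) pmin(lo[[ax]] + 1, d[ax] - 1))
      g <- function(ix, iy, iz) v$data[cbind(
        rep(ix + 1, times = d[2] * d[3]),
        rep(rep(iy + 1, each = d[1]), times = d[3]),
        rep(iz + 1, each = d[1] * d[2]))]
      fx <- rep(fr[[1]], times = d[2] * d[3])
      fy <- rep(rep(fr[[2]], each = d[1]), times = d[3])
      fz <- rep(fr[[3]], each = d[1] * d[2])
      out <- array(
        g(lo[[1]], lo[[2]], lo[[3]]) * (1 - fx) * (1 - fy) * (1 - fz) +
        g(hi[[1]], lo[[2]], lo[[3]]) * fx * (1 - fy) * (1 - fz) +
        g(lo[[1]], hi[[2]], lo[[3]]) * (1 - fx) * fy * (1 - fz) +
        g(hi[[1]], hi[[2]], lo[[3]]) * fx * fy * (1 - fz) +
        g(lo[[1]], lo[[2]], hi[[3]]) * (1 - fx) * (1 - fy) * fz +
        g(hi[[1]], lo[[2]], hi[[3]]) * fx * (1 - fy) * fz +
        g(lo[[1]], hi[[2]], hi[[3]]) * (1 - fx) * fy * fz +
        g(hi[[1]], hi[[2]], hi[[3]]) * fx * fy * fz, d)
    }
    out <- array(monotone_warp(out, p$histogram_warp_strength), d)
    shift <- runif(1, p$intensity_shift_range[1], p$intensity_shift_range[2])
    out <- out + shift * sd(out)
    if (p$noise_sd > 0)
      out <- out + array(rnorm(length(out), 0, p$noise_sd), d)
    volume(out, v$spacing_mm, v$origin)
  })
}

#' Sliding-window patch inference
#'
#' Tiles the volume into overlapping patches, applies a patch predictor to
#' each, and averages overlapping per-class probabilities with uniform
#' weights. Volumes smaller than the patch are zero-padded, predicted once,
#' and cropped back. Every voxel is covered at least once.
#'
#' @param v a `pv_volume`.
#' @param predictor function taking a 3D patch array and returning a 4D
#'   array `c(patch_shape, n_classes)` of per-voxel class probabilities.
#' @param patch_shape integer triple (default `c(384, 384, 24)`, the study's
#'   training patch).
#' @param overlap fractional overlap between adjacent windows in `[0, 1)`.
#' @return A [soft_prediction()] over the full volume.
#' @export
sliding_window_predict <- function(v, predictor,
                                   patch_shape = c(384, 384, 24),
                                   overlap = 0.5) {
  stopifnot(inherits(v, "pv_volume"), is.function(predictor))
  patch_shape <- as.integer(patch_shape)
  if (overlap < 0 || overlap >= 1) stopf("`overlap` must be in [0, 1)")
  d0 <- dim(v$data)
  pad <- pmax(patch_shape - d0, 0L)
  a <- v$data
  if (any(pad > 0L)) {
    big <- array(0, d0 + pad)
    big[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3])] <- a
    a <- big
  }
  d <- dim(a)
  starts <- lapply(1:3, function(ax) {
    step <- max(1L, as.integer(round(patch_shape[ax] * (1 - overlap))))
    s <- seq.int(1L, max(1L, d[ax] - patch_shape[ax] + 1L), by = step)
    unique(c(s, d[ax] - patch_shape[ax] + 1L))
  })
  first <- predictor(a[seq_len(patch_shape[1]), seq_len(patch_shape[2]),
                       seq_len(patch_shape[3]), drop = FALSE])
  if (length(dim(first)) != 4L ||
      !all(dim(first)[1:3] == patch_shape))
    stopf("predictor output shape %s does not match patch %s + classes",
          paste(dim(first), collapse = "x"),
          paste(patch_shape, collapse = "x"))
  ncls <- dim(first)[4]
  classes <- dimnames(first)[[4]] %||% paste0("class", seq_len(ncls) - 1L)
  acc <- array(0, c(d, ncls))
  cnt <- array(0, d)
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    ix <- sx:(sx + patch_shape[1] - 1L)
    iy <- sy:(sy + patch_shape[2] - 1L)
    iz <- sz:(sz + patch_shape[3] - 1L)
    pr <- if (sx == starts[[1]][1] && sy == starts[[2]][1] &&
              sz == starts[[3]][1]) first
          else predictor(a[ix, iy, iz, drop = FALSE])
    if (length(dim(pr)) != 4L || !all(dim(pr)[1:3] == patch_shape) ||
        dim(pr)[4] != ncls)
      stopf("predictor output shape changed between windows")
    acc[ix, iy, iz, ] <- acc[ix, iy, iz, , drop = FALSE] + pr
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  probs <- acc / as.vector(cnt)
  probs <- probs[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), ,
                 drop = FALSE]
  soft_prediction(probs, classes = classes, spacing_mm = v$spacing_mm)
}
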