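#' Soft per-class segmentation prediction
#'
#' @param probs 4D array `c(grid, n_classes)` of per-voxel class
#'   probabilities in `[0, 1]` summing to 1 per voxel (within 1e-5).
#' @param classes character vector of class names; the first is conventionally
#'   `"background"`.
#' @param spacing_mm voxel spacing of the underlying grid.
#' @return Object of class `pv_soft_prediction`.
#' @export
soft_prediction <- function(probs, classes, spacing_mm = c(0.6, 0.6, 6.0)) {
  stopifnot(is.array(probs), length(dim(probs)) == 4L)
  if (dim(probs)[4] != length(classes))
    stopf("`classes` length must equal dim(probs)[4]")
  if (min(probs) < -1e-8 || max(probs) > 1 + 1e-8)
    stopf("probabilities must lie in [0, 1]")
  tot <- apply(probs, 1:3, sum)
  if (max(abs(tot - 1)) > 1e-5)
    stopf("per-voxel class probabilities must sum to 1 (max dev %.2e)",
          max(abs(tot - 1)))
  structure(list(probs = probs, classes = as.character(classes),
                 spacing_mm = as.double(spacing_mm)),
            class = "pv_soft_prediction")
}

#' One-hot soft prediction from a label mask
#'
#' @param target integer array of class indices (0 = first class).
#' @param classes class names.
#' @param spacing_mm grid spacing.
#' @return `pv_soft_prediction` with probabilities 0/1.
#' @export
one_hot <- function(target, classes, spacing_mm = c(0.6, 0.6, 6.0)) {
  d <- dim(target)
  probs <- array(0, c(d, length(classes)))
  for (k in seq_along(classes))
    probs[, , , k] <- as.double(target == (k - 1L))
  soft_prediction(probs, classes, spacing_mm)
}

#' Loss configuration for segmentation training
#'
#' Focal and Dice loss combined in a 1:1 ratio; the boundary term is added
#' for cyst segmentation (where lesion boundaries are otherwise poorly
#' delineated).
#'
#' @param focal_gamma focusing parameter of the focal loss (default 2).
#' @param focal_dice_ratio length-2 positive weights `(focal, dice)`;
#'   default `c(1, 1)`.
#' @param use_boundary add the signed-distance boundary term?
#' @param boundary_weight weight of the boundary term when used.
#' @return List of class `pv_loss_config`.
#' @export
loss_config <- function(focal_gamma = 2.0, focal_dice_ratio = c(1, 1),
                        use_boundary = FALSE, boundary_weight = 1.0) {
  if (focal_gamma < 0) stopf("`focal_gamma` must be >= 0")
  if (length(focal_dice_ratio) != 2L || any(focal_dice_ratio <= 0))
    stopf("`focal_dice_ratio` must be two positive weights")
  structure(list(focal_gamma = focal_gamma,
                 focal_dice_ratio = as.double(focal_dice_ratio),
                 use_boundary = isTRUE(use_boundary),
                 boundary_weight = as.double(boundary_weight)),
            class = "pv_loss_config")
}

# resolve a target argument (pv_label_mask or 0-based integer array) to
# class indices matching pred$classes
target_indices <- function(pred, target) {
  classes <- pred$classes
  if (inherits(target, "pv_label_mask")) {
    idx <- array(0L, dim(target$data))
    for (k in seq_along(classes)) {
      if (classes[k] == "background") next
      if (!classes[k] %in% names(target$labels %||% c()))
        stopf("target mask lacks a '%s' label", classes[k])
      idx[target$data == target$labels[[classes[k]]]] <- k - 1L
    }
    target <- idx
  }
  if (!all(dim(target) == dim(pred$probs)[1:3]))
    stopf("prediction and target shapes differ")
  target
}

#' Soft Dice loss
#'
#' `1 -` mean over foreground classes of the soft Dice overlap
#' `2 * sum(p*g) / (sum(p) + sum(g))`. A class absent from both prediction
#' and target counts as perfectly predicted.
#'
#' @param pred a [soft_prediction()].
#' @param target matching `pv_label_mask` or 0-based integer index array.
#' @return Scalar in `[0, 1]`.
#' @export
dice_loss <- function(pred, target) {
  stopifnot(inherits(pred, "pv_soft_prediction"))
  t <- target_indices(pred, target)
  fg <- which(pred$classes != "background")
  if (length(fg) == 0) stopf("prediction has no foreground classes")
  dices <- vapply(fg, function(k) {
    p <- as.vector(pred$probs[, , , k, drop = FALSE])
    g <- as.double(t == (k - 1L))
    den <- sum(p) + sum(g)
    if (den == 0) 1 else 2 * sum(p * g) / den
  }, numeric(1))
  1 - mean(dices)
}

#' Focal loss
#'
#' Mean over voxels of `-(1 - p_t)^gamma * log(p_t)` where `p_t` is the
#' predicted probability of the true class, clipped to `[1e-7, 1 - 1e-7]`.
#' With `gamma = 0` this is the cross-entropy.
#'
#' @inheritParams dice_loss
#' @param gamma focusing parameter, >= 0.
#' @return Nonnegative scalar.
#' @export
focal_loss <- function(pred, target, gamma = 2.0) {
  stopifnot(inherits(pred, "pv_soft_prediction"), gamma >= 0)
  t <- target_indices(pred, target)
  d <- dim(pred$probs)
  nvox <- prod(d[1:3])
  pm <- matrix(pred$probs, nvox, d[4])
  pt <- pm[cbind(seq_len(nvox), as.integer(t) + 1L)]
  pt <- pmin(pmax(pt, 1e-7), 1 - 1e-7)
  mean(-(1 - pt)^gamma * log(pt))
}

# signed Euclidean distance map (mm): negative inside the mask, positive
# outside, zero-crossing at the boundary voxels
signed_distance_mm <- function(mask, spacing_mm) {
  d <- dim(mask)
  d_out <- .cpp_edt(as.logical(mask), as.integer(d), as.double(spacing_mm))
  d_in <- .cpp_edt(!as.logical(mask), as.integer(d), as.double(spacing_mm))
  array(d_out - d_in, d)
}

#' Signed-distance boundary loss
#'
#' Mean over voxels (and foreground classes) of the predicted foreground
#' probability times the signed Euclidean distance (mm) to the target
#' boundary (negative inside the target, positive outside). Predictions
#' concentrating mass outside the target are penalized; the one-hot truth
#' attains the minimum among mass-preserving perturbations.
#'
#' @inheritParams dice_loss
#' @param spacing_mm grid spacing used for physical distances.
#' @return Signed scalar (0 for an empty target, with a warning).
#' @export
boundary_loss <- function(pred, target, spacing_mm = NULL) {
  stopifnot(inherits(pred, "pv_soft_prediction"))
  sp <- spacing_mm %||% pred$spacing_mm
  t <- target_indices(pred, target)
  fg <- which(pred$classes != "background")
  vals <- vapply(fg, function(k) {
    g <- t == (k - 1L)
    if (!any(g)) {
      warnf("boundary loss: empty target for class '%s', defined as 0",
            pred$classes[k])
      return(0)
    }
    phi <- signed_distance_mm(g, sp)
    mean(as.vector(pred$probs[, , , k, drop = FALSE]) * as.vector(phi))
  }, numeric(1))
  mean(vals)
}

#' Combined segmentation loss
#'
#' Focal and Dice loss in the configured (default 1:1) ratio, plus the
#' boundary term when `cfg$use_boundary`.
#'
#' @inheritParams dice_loss
#' @param cfg a [loss_config()].
#' @param spacing_mm grid spacing for the boundary term.
#' @return Scalar loss.
#' @export
combined_loss <- function(pred, target, cfg = loss_config(),
                          spacing_mm = NULL) {
  stopifnot(inherits(cfg, "pv_loss_config"))
  out <- cfg$focal_dice_ratio[1] * focal_loss(pred, target, cfg$focal_gamma) +
    cfg$focal_dice_ratio[2] * dice_loss(pred, target)
  if (cfg$use_boundary)
    out <- out + cfg$boundary_weight * boundary_loss(pred, target, spacing_mm)
  out
}

#' Ensemble-mean prediction
#'
#' Voxel-wise arithmetic mean of the member probabilities (the final mask is
#' the argmax). Members differing only by random initialization mirror the
#' five-model ensembles used for both lesion models.
#'
#' @param models list of predictors: each a function mapping a `pv_volume`
#'   to a `pv_soft_prediction` (or bare 4D probability array).
#' @param v input `pv_volume`.
#' @return `pv_soft_prediction` of the ensemble mean.
#' @export
ensemble_predict <- function(models, v) {
  if (length(models) < 1) stopf("need at least one model")
  preds <- lapply(models, function(m) {
    out <- m(v)
    if (inherits(out, "pv_soft_prediction")) out
    else soft_prediction(out,
                         dimnames(out)[[4]] %||%
                           paste0("class", seq_len(dim(out)[4]) - 1L),
                         v$spacing_mm)
  })
  classes <- preds[[1]]$classes
  for (p in preds[-1])
    if (!identical(p$classes, classes))
      stopf("ensemble members disagree on the class set")
  acc <- preds[[1]]$probs
  for (p in preds[-1]) acc <- acc + p$probs
  soft_prediction(acc / length(preds), classes, v$spacing_mm)
}

#' Hard label mask from a soft prediction
#'
#' @param pred a `pv_soft_prediction`.
#' @return `pv_label_mask` with labels named after the foreground classes.
#' @export
argmax_mask <- function(pred) {
  stopifnot(inherits(pred, "pv_soft_prediction"))
  d <- dim(pred$probs)
  pm <- matrix(pred$probs, prod(d[1:3]), d[4])
  idx <- max.col(pm, ties.method = "first") - 1L
  fg <- pred$classes != "background"
  label_mask(array(idx, d[1:3]), pred$spacing_mm,
             labels = setNames(seq_along(pred$classes)[fg] - 1L,
                               pred$classes[fg]))
}
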