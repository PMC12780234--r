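#' Dice similarity coefficient of two masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks are defined as DSC 1 and
#' carry a `both_empty` attribute so summaries can exclude them.
#'
#' @param a,b logical arrays or `pv_label_mask`s (nonzero = foreground) of
#'   identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  ma <- if (inherits(a, "pv_label_mask")) a$data != 0L else a != 0
  mb <- if (inherits(b, "pv_label_mask")) b$data != 0L else b != 0
  if (!all(dim(ma) == dim(mb))) stopf("mask shapes differ")
  sa <- sum(ma); sb <- sum(mb)
  if (sa + sb == 0) return(structure(1, both_empty = TRUE))
  2 * sum(ma & mb) / (sa + sb)
}

#' Axis-aligned 3D bounding box
#'
#' Half-open voxel-coordinate box `[lo, hi)`, `lo < hi` per axis.
#'
#' @param lo,hi numeric triples.
#' @return List of class `pv_box`.
#' @export
box3 <- function(lo, hi) {
  lo <- as.double(lo); hi <- as.double(hi)
  if (length(lo) != 3 || length(hi) != 3 || any(hi <= lo))
    stopf("box needs lo < hi on all three axes")
  structure(list(lo = lo, hi = hi), class = "pv_box")
}

#' A detection: bounding box plus confidence
#'
#' @param box a [box3()].
#' @param confidence scalar in `[0, 1]`.
#' @return List of class `pv_detection`.
#' @export
detection <- function(box, confidence) {
  stopifnot(inherits(box, "pv_box"))
  if (confidence < 0 || confidence > 1) stopf("confidence must be in [0, 1]")
  structure(list(bbox = box, confidence = as.double(confidence)),
            class = "pv_detection")
}

#' Intersection-over-union of two boxes
#'
#' Volume IoU in voxel units; disjoint boxes give 0, identical boxes 1.
#' Symmetric in its arguments.
#'
#' @param a,b [box3()] objects.
#' @return Scalar in `[0, 1]`.
#' @export
iou_boxes <- function(a, b) {
  stopifnot(inherits(a, "pv_box"), inherits(b, "pv_box"))
  inter <- prod(pmax(pmin(a$hi, b$hi) - pmax(a$lo, b$lo), 0))
  va <- prod(a$hi - a$lo)
  vb <- prod(b$hi - b$lo)
  inter / (va + vb - inter)
}

#' Bounding boxes of the connected components of a mask
#'
#' One tight half-open box per 26-connected component of the binarized
#' mask, ordered by component size descending.
#'
#' @param mask logical array or `pv_label_mask`.
#' @param min_voxels drop components smaller than this.
#' @return List of [box3()] with a `voxels` attribute each.
#' @export
mask_bounding_boxes <- function(mask, min_voxels = 1) {
  m <- if (inherits(mask, "pv_label_mask")) mask$data != 0L else mask != 0
  d <- dim(m)
  if (sum(m) == 0) return(list())
  lab <- array(.cpp_label3d(as.logical(m), as.integer(d), 26L), d)
  sizes <- tabulate(lab[lab > 0L])
  out <- list()
  for (comp in order(sizes, decreasing = TRUE)) {
    if (sizes[comp] < min_voxels) next
    idx <- which(lab == comp, arr.ind = TRUE)
    b <- box3(apply(idx, 2, min) - 1, apply(idx, 2, max))
    attr(b, "voxels") <- sizes[comp]
    out[[length(out) + 1L]] <- b
  }
  out
}

#' Greedy detection-truth matching
#'
#' Predictions are visited in descending confidence; each claims the
#' unmatched ground-truth box of highest IoU provided the IoU reaches the
#' threshold (default 0.01, reflecting the high shape variability of the
#' lesions in 3D). Each truth is matched at most once; unmatched predictions
#' are false positives and unmatched truths false negatives.
#'
#' @param preds list of [detection()].
#' @param truths list of [box3()].
#' @param iou_threshold TP criterion, `IoU >= iou_threshold`, in `(0, 1]`.
#' @return List with logical `pred_tp` (in the original pred order),
#'   integer `pred_match` (matched truth index or NA), `truth_matched`
#'   logical, and TP/FP/FN counts.
#' @export
match_detections <- function(preds, truths, iou_threshold = 0.01) {
  if (iou_threshold <= 0 || iou_threshold > 1)
    stopf("`iou_threshold` must be in (0, 1]")
  np <- length(preds); nt <- length(truths)
  conf <- vapply(preds, `[[`, 0, "confidence")
  ord <- order(conf, decreasing = TRUE)
  tp <- logical(np)
  match_idx <- rep(NA_integer_, np)
  taken <- logical(nt)
  for (i in ord) {
    if (nt == 0) break
    ious <- vapply(seq_len(nt), function(j)
      if (taken[j]) -1 else iou_boxes(preds[[i]]$bbox, truths[[j]]), 0)
    j <- which.max(ious)
    if (length(j) && ious[j] >= iou_threshold) {
      tp[i] <- TRUE
      taken[j] <- TRUE
      match_idx[i] <- j
    }
  }
  list(pred_tp = tp, pred_match = match_idx, truth_matched = taken,
       tp = sum(tp), fp = sum(!tp), fn = sum(!taken))
}

#' Average precision of lesion detection
#'
#' Pools predictions over all images, orders them by descending confidence,
#' and integrates the precision-recall step curve (`AP = sum(dR * P)`).
#' With the single lesion class, mAP equals AP. Optionally also reports the
#' operating point (recall, precision) at a confidence cut.
#'
#' @param preds list of per-image prediction lists (each a list of
#'   [detection()]); a plain list of detections is treated as one image.
#' @param truths matching list of per-image truth-box lists.
#' @param iou_threshold TP criterion (default 0.01).
#' @param confidence_threshold optional cut for the reported operating
#'   point.
#' @return List with `ap`, `n_truth`, the pooled `curve` data.frame and,
#'   when requested, `recall`/`precision` at the cut.
#' @export
average_precision <- function(preds, truths, iou_threshold = 0.01,
                              confidence_threshold = NULL) {
  single <- length(preds) > 0 && inherits(preds[[1]], "pv_detection")
  if (single || (length(preds) == 0 && length(truths) > 0 &&
                 inherits(truths[[1]], "pv_box"))) {
    preds <- list(preds); truths <- list(truths)
  }
  if (length(preds) != length(truths))
    stopf("`preds` and `truths` must have one entry per image")
  n_truth <- sum(lengths(truths))
  if (n_truth == 0) stopf("average precision undefined with zero ground-truth lesions")
  conf <- c(); is_tp <- c()
  for (im in seq_along(preds)) {
    m <- match_detections(preds[[im]], truths[[im]], iou_threshold)
    conf <- c(conf, vapply(preds[[im]], `[[`, 0, "confidence"))
    is_tp <- c(is_tp, m$pred_tp)
  }
  ord <- order(conf, decreasing = TRUE)
  conf <- conf[ord]; is_tp <- is_tp[ord]
  cum_tp <- cumsum(is_tp)
  prec <- cum_tp / seq_along(cum_tp)
  rec <- cum_tp / n_truth
  ap <- sum(diff(c(0, rec)) * prec)
  out <- list(ap = ap, n_truth = n_truth,
              curve = data.frame(confidence = conf, recall = rec,
                                 precision = prec))
  if (!is.null(confidence_threshold)) {
    keep <- conf >= confidence_threshold
    tp <- sum(is_tp[keep])
    out$recall <- tp / n_truth
    out$precision <- if (any(keep)) tp / sum(keep) else NA_real_
  }
  out
}

#' Reader sensitivity (recall) against a truth table
#'
#' Per reader, TP / (TP + FN) over positive images, plus the mean across
#' readers. With zero positive images the sensitivity is undefined and
#' reported as NA with `undefined = TRUE` (the "-" convention of reader
#' studies lacking positive samples).
#'
#' @param assessments data.frame with `reader_id`, `image_id`, `value`.
#' @param truth data.frame with `image_id`, `value`.
#' @param positive values counted as positive (default: `TRUE`, `1`,
#'   `"mild"`, `"severe"`, `"positive"`).
#' @return List with `per_reader`, `mean`, `n_positive`, `undefined`.
#' @export
sensitivity <- function(assessments, truth,
                        positive = c("TRUE", "1", "mild", "severe",
                                     "positive")) {
  need <- c("reader_id", "image_id", "value")
  if (!all(need %in% names(assessments)))
    stopf("`assessments` needs columns %s", paste(need, collapse = ", "))
  if (!all(c("image_id", "value") %in% names(truth)))
    stopf("`truth` needs columns image_id, value")
  is_pos <- function(v) as.character(v) %in% positive
  tr_pos <- setNames(is_pos(truth$value), truth$image_id)
  if (!all(assessments$image_id %in% names(tr_pos)))
    stopf("assessments reference image ids absent from the truth table")
  n_pos <- sum(tr_pos)
  if (n_pos == 0)
    return(list(per_reader = NULL, mean = NA_real_, n_positive = 0L,
                undefined = TRUE))
  per <- tapply(seq_len(nrow(assessments)), assessments$reader_id,
                function(rows) {
      sub <- assessments[rows, ]
      pos_imgs <- sub$image_id[tr_pos[sub$image_id]]
      sub <- sub[tr_pos[sub$image_id], ]
      if (nrow(sub) == 0) return(NA_real_)
      mean(is_pos(sub$value))
    })
  list(per_reader = per, mean = mean(per, na.rm = TRUE),
       n_positive = as.integer(n_pos), undefined = FALSE)
}

#' Cohen's kappa
#'
#' Unweighted chance-corrected agreement `(p_o - p_e) / (1 - p_e)` between
#' two categorical raters over a shared category set (binary for adhesion,
#' ternary none/mild/severe for plaque grading). Two identical constant
#' series (chance agreement 1) are defined as kappa 1 with a `degenerate`
#' attribute.
#'
#' @param x,y equal-length categorical vectors (length >= 2).
#' @return Scalar in `[-1, 1]`.
#' @export
cohens_kappa <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stopf("`x` and `y` must have equal length >= 2")
  lev <- sort(unique(c(as.character(x), as.character(y))))
  x <- factor(as.character(x), levels = lev)
  y <- factor(as.character(y), levels = lev)
  tab <- table(x, y) / length(x)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (abs(1 - pe) < 1e-12) {
    if (po == 1) return(structure(1, degenerate = TRUE))
    stopf("kappa undefined: expected agreement 1 with observed disagreement")
  }
  (po - pe) / (1 - pe)
}

#' Pearson correlation with validation
#'
#' Standard product-moment correlation (used to compare automated depth and
#' axis measurements against radiologist references).
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return Scalar in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stopf("`x` and `y` must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stopf("correlation undefined for zero-variance input")
  stats::cor(x, y)
}
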