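stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("[stage:%s] %s", name, conditionMessage(e)))
}

# plaque detections of a soft prediction: the lesion probability map is
# lightly smoothed (suppressing single-voxel noise peaks) and thresholded at
# `prob_floor` times its maximum -- detection operates on the probability
# map, not the argmax, so weakly-expressed lesions still localize. One
# detection per 26-connected component (>= 2 voxels); confidence = mean
# smoothed probability inside the component's box, relative to the image
# maximum.
plaque_detections <- function(pred, prob_floor = 0.5) {
  k <- which(pred$classes == "plaque")
  pp <- gaussian_smooth3d(pred$probs[, , , k], c(1, 1, 0.5))
  top <- max(pp)
  if (top <= 0) return(list())
  boxes <- mask_bounding_boxes(pp > prob_floor * top, min_voxels = 2)
  lapply(boxes, function(b) {
    lo <- b$lo + 1; hi <- b$hi
    conf <- mean(pp[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]) / top
    detection(b, max(min(conf, 1), 0))
  })
}

#' End-to-end demonstration on a generated phantom cohort
#'
#' Generates a cohort, trains the toy segmenter, trains the adhesion
#' classifier, measures plaques and cysts, and evaluates everything:
#' per-organ DSC, plaque-detection AP at IoU 0.01, depth/severity recovery
#' against ground truth, cyst axis recovery, pre/post volume changes and
#' cross-validated adhesion metrics. Deterministic under `seed`.
#'
#' @param seed integer master seed.
#' @param config a [default_config()] (the `demo` section sets cohort size,
#'   grid and epochs).
#' @param out_dir optional directory; when given, a JSON report and a
#'   per-sample CSV are written there.
#' @return Report list (invisibly when `out_dir` is used).
#' @export
run_demo <- function(seed = 0, config = default_config(), out_dir = NULL) {
  dm <- config$demo
  cohort <- stage("phantom", generate_cohort(
    dm$n, seed = seed + 1, image_shape = dm$image_shape,
    spacing_mm = dm$spacing_mm))

  n_train <- min(dm$train_samples, length(cohort) - 1)
  train_set <- cohort[seq_len(n_train)]
  test_set <- cohort[(n_train + 1):length(cohort)]

  cfg <- loss_config(focal_gamma = config$loss$focal_gamma,
                     focal_dice_ratio = config$loss$focal_dice_ratio,
                     use_boundary = config$loss$use_boundary)
  model <- stage("train", train_toy_segmenter(train_set, cfg,
                                              epochs = dm$epochs,
                                              seed = seed + 2))
  loss_hist <- model$loss_history

  seg <- stage("segment-eval", {
    per_class <- list()
    preds <- list()
    for (i in seq_along(test_set)) {
      s <- test_set[[i]]
      pred <- predict_segmentation(model, s$t2_volume)
      preds[[i]] <- pred
      hard <- argmax_mask(pred)
      tgt <- seg_target(s$organ_mask)
      for (k in seq_along(model$classes)[-1]) {
        d <- dsc(hard$data == (k - 1L), tgt == (k - 1L))
        if (!isTRUE(attr(d, "both_empty")))
          per_class[[model$classes[k]]] <-
            c(per_class[[model$classes[k]]], as.double(d))
      }
    }
    list(mean_dsc = vapply(per_class, mean, 0), preds = preds)
  })

  det <- stage("detect-eval", {
    pl <- lapply(seg$preds, plaque_detections)
    tl <- lapply(test_set, function(s)
      mask_bounding_boxes(mask_of(s$organ_mask, "plaque")))
    if (sum(lengths(tl)) == 0) list(ap = NA_real_)
    else average_precision(pl, tl, config$detection_iou_threshold)
  })

  morpho <- stage("morphometry", {
    tol <- dm$spacing_mm[1] # one in-plane voxel
    errs <- vapply(cohort, function(s) {
      m <- plaque_depth(s$organ_mask,
                        config$contact_dist_voxels * dm$spacing_mm[1])
      c(abs(m$depth_mm - s$truth$plaque_depth_mm),
        as.numeric(identical(m$severity, s$truth$severity)))
    }, numeric(2))
    oec_ok <- c()
    for (s in cohort) {
      if (is.null(s$truth$oec_axes_mm)) next
      ax <- oec_axes(s$oec_mask)[[1]]
      oec_ok <- c(oec_ok,
        abs(ax$major_mm - s$truth$oec_axes_mm[1]) / s$truth$oec_axes_mm[1] <= 0.05 &&
        abs(ax$minor_mm - s$truth$oec_axes_mm[2]) / s$truth$oec_axes_mm[2] <= 0.05)
    }
    pairs <- list()
    ids <- vapply(cohort, `[[`, "", "patient_id")
    for (pid in unique(ids[duplicated(ids)])) {
      pp <- cohort[ids == pid]
      pairs[[pid]] <- volume_change(pp[[1]]$oec_mask, pp[[2]]$oec_mask)
    }
    list(depth_recovery_rate = mean(errs[1, ] <= tol + 1e-9),
         severity_accuracy = mean(errs[2, ]),
         oec_axis_recovery_rate = if (length(oec_ok)) mean(oec_ok) else NA,
         n_pairs = length(pairs),
         mean_volume_change_mm3 = if (length(pairs))
           mean(vapply(pairs, `[[`, 0, "delta_mm3")) else NA)
  })

  adh <- stage("adhesion", {
    ds <- cohort_adhesion_dataset(cohort)
    cv <- evaluate_cv(ds, "uterus-rectum", k = config$adhesion$cv_folds,
                      seed = seed + 3,
                      hyperparams = config$adhesion$hyperparams,
                      threshold = config$adhesion$threshold, n_boot = 500)
    list(location = cv$location, recall = cv$recall,
         precision = cv$precision, f1 = cv$f1,
         n_positive = cv$n_positive)
  })

  report <- list(
    seed = seed,
    n_samples = length(cohort),
    training = list(first_epoch_loss = loss_hist[1],
                    final_epoch_loss = loss_hist[length(loss_hist)],
                    loss_decreased = loss_hist[length(loss_hist)] <
                      loss_hist[1],
                    loss_history = loss_hist),
    segmentation = list(mean_dsc = as.list(seg$mean_dsc)),
    detection = list(ap = det$ap),
    morphometry = morpho,
    adhesion = adh)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "demo_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    truths <- do.call(rbind, lapply(cohort, function(s)
      data.frame(patient_id = s$patient_id,
                 image_id = s$image_id %||% s$patient_id,
                 depth_mm = s$truth$plaque_depth_mm,
                 severity = s$truth$severity)))
    write.csv(truths, file.path(out_dir, "cohort_truth.csv"),
              row.names = FALSE)
    return(invisible(report))
  }
  report
}
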