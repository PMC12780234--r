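#' Default run configuration
#'
#' All pipeline constants surfaced as named defaults: the working voxel
#' spacing (0.6 x 0.6 x 6.0 mm), training patch (384 x 384 x 24 voxels),
#' augmentation ranges, loss settings, the detection IoU threshold (0.01),
#' the 5 mm severity boundary and the 0.5 adhesion decision threshold.
#' Values can be overridden from a YAML file.
#'
#' @param path optional YAML file whose entries override the defaults.
#' @return Nested list of class `pv_config`.
#' @export
default_config <- function(path = NULL) {
  cfg <- list(
    spacing_mm = c(0.6, 0.6, 6.0),
    patch_shape = c(384, 384, 24),
    sliding_window_overlap = 0.5,
    augmentation = list(zoom_range = c(0.9, 1.2),
                        intensity_shift_range = c(-0.1, 0.1),
                        noise_sd = 0.1,
                        histogram_warp_strength = 0.3),
    loss = list(focal_gamma = 2.0, focal_dice_ratio = c(1, 1),
                use_boundary = FALSE, boundary_weight = 1.0),
    ensemble_size = 5,
    detection_iou_threshold = 0.01,
    severity_boundary_mm = 5.0,
    contact_dist_voxels = 1.5,
    adhesion = list(threshold = 0.5, cv_folds = 5,
                    hyperparams = list(nrounds = 200, max_depth = 4,
                                       eta = 0.1)),
    demo = list(n = 50, image_shape = c(64, 64, 12),
                spacing_mm = c(1.8, 1.8, 10.0), epochs = 100,
                train_samples = 8)
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  structure(cfg, class = c("pv_config", "list"))
}

#' Write the active configuration to YAML
#'
#' @param cfg a `pv_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
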