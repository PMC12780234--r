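# pelvamp default run configuration (mirrors default_config()); values here
# override the built-in defaults when passed via --config.
spacing_mm: [0.6, 0.6, 6.0]       # working voxel grid, mm
patch_shape: [384, 384, 24]       # training patch, voxels
sliding_window_overlap: 0.5
augmentation:
  zoom_range: [0.9, 1.2]
  intensity_shift_range: [-0.1, 0.1]   # in units of the image SD
  noise_sd: 0.1
  histogram_warp_strength: 0.3
loss:
  focal_gamma: 2.0
  focal_dice_ratio: [1, 1]
  use_boundary: false               # enabled for cyst segmentation
  boundary_weight: 1.0
ensemble_size: 5
detection_iou_threshold: 0.01
severity_boundary_mm: 5.0
contact_dist_voxels: 1.5
adhesion:
  threshold: 0.5
  cv_folds: 5
  hyperparams: {nrounds: 200, max_depth: 4, eta: 0.1}
demo:
  n: 50
  image_shape: [64, 64, 12]
  spacing_mm: [1.8, 1.8, 10.0]
  epochs: 100
  train_samples: 8
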