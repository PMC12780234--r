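# deterministic random blob masks used by the shape-feature oracle tests:
# a uniform random field is Gaussian-smoothed, thresholded at its 80th
# percentile, and reduced to its largest 26-connected component
blob_mask <- function(seed, shape = c(40, 40, 40), field_sigma = 5, q = 0.8) {
  set.seed(seed)
  field <- pelvamp:::gaussian_smooth3d(array(runif(prod(shape)), shape),
                                       rep(field_sigma, 3))
  m <- field > quantile(field, q)
  lab <- array(pelvamp:::.cpp_label3d(as.logical(m), as.integer(shape), 26L),
               shape)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# spacing assigned to oracle blob `seed`: isotropic for most, anisotropic
# for the last six
blob_spacing <- function(seed) {
  if (seed <= 14) c(1, 1, 1) else c(0.75, 0.75, 1.5)
}
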