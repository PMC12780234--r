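# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_length3 <- function(x, what) {
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x)))
    stopf("%s must be a finite numeric triple", what)
  x
}

# sampled Gaussian kernel, radius 4*sigma (matches the usual truncated
# discrete kernel), normalized to sum 1
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(4 * sigma + 0.5))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# separable Gaussian smoothing of a 3D array, sigma in voxels per axis,
# zero boundary condition
gaussian_smooth3d <- function(a, sigma) {
  sigma <- rep(sigma, length.out = 3L)
  d <- dim(a)
  out <- as.double(a)
  for (ax in 0:2) {
    if (sigma[ax + 1L] <= 0) next
    k <- gaussian_kernel(sigma[ax + 1L])
    out <- .cpp_convolve_axis(out, as.integer(d), as.double(k), ax)
  }
  array(out, d)
}

# voxel-center world coordinates (mm) of a grid; 0-based index convention
# world = index * spacing + origin
axis_coords <- function(n, spacing, origin = 0) (seq_len(n) - 1) * spacing + origin

# n x 3 matrix of all voxel-center coordinates (column-major voxel order)
grid_coords <- function(dims, spacing, origin = c(0, 0, 0)) {
  cbind(
    rep(axis_coords(dims[1], spacing[1], origin[1]), times = dims[2] * dims[3]),
    rep(rep(axis_coords(dims[2], spacing[2], origin[2]), each = dims[1]), times = dims[3]),
    rep(axis_coords(dims[3], spacing[3], origin[3]), each = dims[1] * dims[2])
  )
}

# logical array of boundary voxels: foreground with a 6-neighbour background
# (or touching the array edge)
boundary_voxels <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  core <- function(di, dj, dk)
    pad[(2:(d[1] + 1L)) + di, (2:(d[2] + 1L)) + dj, (2:(d[3] + 1L)) + dk]
  interior <- core(-1L, 0L, 0L) & core(1L, 0L, 0L) &
    core(0L, -1L, 0L) & core(0L, 1L, 0L) &
    core(0L, 0L, -1L) & core(0L, 0L, 1L)
  mask & !interior
}

# 2D analogue: foreground pixels with a 4-neighbour background (8-connected
# contour of the region)
contour_pixels <- function(mask2d) {
  d <- dim(mask2d)
  pad <- matrix(FALSE, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- mask2d
  core <- function(di, dj) pad[(2:(d[1] + 1L)) + di, (2:(d[2] + 1L)) + dj]
  interior <- core(-1L, 0L) & core(1L, 0L) & core(0L, -1L) & core(0L, 1L)
  mask2d & !interior
}

# run fn() with a temporarily-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}
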