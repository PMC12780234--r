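# small geometric fixtures shared across tests

# rasterize a rotated rectangle (center cx/cy mm, half-sizes hx/hy mm,
# rotation theta) on an n x n pixel grid with the given pixel size
raster_rect <- function(n, px, cx, cy, hx, hy, theta = 0) {
  co <- (seq_len(n) - 1) * px
  g <- expand.grid(x = co, y = co)
  xr <- (g$x - cx) * cos(theta) + (g$y - cy) * sin(theta)
  yr <- -(g$x - cx) * sin(theta) + (g$y - cy) * cos(theta)
  matrix(abs(xr) <= hx & abs(yr) <= hy, n, n)
}

# rasterize a filled ellipse (semi-axes a/b mm, rotation theta) on an
# n x n pixel grid
raster_ellipse <- function(n, px, a, b, theta = 0, cx = NULL, cy = NULL) {
  co <- (seq_len(n) - 1) * px
  cx <- cx %||% mean(range(co))
  cy <- cy %||% mean(range(co))
  g <- expand.grid(x = co, y = co)
  xr <- (g$x - cx) * cos(theta) + (g$y - cy) * sin(theta)
  yr <- -(g$x - cx) * sin(theta) + (g$y - cy) * cos(theta)
  matrix((xr / a)^2 + (yr / b)^2 <= 1, n, n)
}

# digitized ball of radius r mm on an isotropic grid
raster_ball <- function(r_mm, spacing = 1, margin = 5) {
  n <- as.integer(ceiling(2 * (r_mm + margin) / spacing))
  co <- (seq_len(n) - 1) * spacing
  c0 <- mean(range(co))
  g <- expand.grid(x = co, y = co, z = co)
  array((g$x - c0)^2 + (g$y - c0)^2 + (g$z - c0)^2 <= r_mm^2, c(n, n, n))
}

# digitized axis-aligned ellipsoid with semi-axes in mm
raster_ellipsoid <- function(semi_mm, spacing = c(1, 1, 1), margin = 4) {
  n <- as.integer(ceiling(2 * (semi_mm + margin) / spacing))
  co <- lapply(1:3, function(ax) (seq_len(n[ax]) - 1) * spacing[ax])
  ctr <- vapply(co, function(x) mean(range(x)), 0)
  g <- expand.grid(x = co[[1]], y = co[[2]], z = co[[3]])
  array(((g$x - ctr[1]) / semi_mm[1])^2 + ((g$y - ctr[2]) / semi_mm[2])^2 +
          ((g$z - ctr[3]) / semi_mm[3])^2 <= 1, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# uniform random boxes and detections for matching/AP oracles
random_boxes <- function(k, span = 8) {
  lapply(seq_len(k), function(i) {
    lo <- runif(3, 0, span)
    box3(lo, lo + runif(3, 0.5, span / 2))
  })
}

random_detections <- function(k, span = 8) {
  boxes <- random_boxes(k, span)
  lapply(boxes, function(b) detection(b, runif(1)))
}

# independent best-first matcher: repeatedly scans all (pred, truth) pairs
# and applies the confidence-descending, max-IoU rule by brute force
brute_best_first <- function(preds, truths, thr) {
  np <- length(preds); nt <- length(truths)
  used_p <- logical(np); used_t <- logical(nt)
  tp <- 0L
  repeat {
    best <- NULL
    for (i in seq_len(np)) {
      if (used_p[i]) next
      if (is.null(best) ||
          preds[[i]]$confidence > preds[[best]]$confidence) best <- i
    }
    if (is.null(best)) break
    used_p[best] <- TRUE
    if (nt == 0) next
    ious <- rep(-1, nt)
    for (j in seq_len(nt)) if (!used_t[j])
      ious[j] <- iou_boxes(preds[[best]]$bbox, truths[[j]])
    j <- which.max(ious)
    if (length(j) && ious[j] >= thr) {
      used_t[j] <- TRUE
      tp <- tp + 1L
    }
  }
  tp
}

# independent AP: explicit enumeration of the precision-recall step curve
brute_ap <- function(conf, is_tp, n_truth) {
  ord <- order(conf, decreasing = TRUE)
  tp <- 0; ap <- 0; prev_rec <- 0; pos <- 0
  for (i in ord) {
    pos <- pos + 1
    tp <- tp + is_tp[i]
    rec <- tp / n_truth
    ap <- ap + (rec - prev_rec) * (tp / pos)
    prev_rec <- rec
  }
  ap
}
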