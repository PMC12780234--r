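test_that("DSC: identity, disjoint, arithmetic and both-empty convention", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, , ] <- TRUE
  expect_equal(dsc(a, a), 1)
  b <- array(FALSE, c(4, 4, 4)); b[3:4, , ] <- TRUE
  expect_equal(dsc(a, b), 0)
  # |A| = |B| = 100, overlap 50 -> 0.5
  x <- array(FALSE, c(10, 10, 2)); x[1:50] <- TRUE
  y <- array(FALSE, c(10, 10, 2)); y[26:75] <- TRUE
  expect_equal(dsc(x, y), 0.5)
  e <- array(FALSE, c(3, 3, 3))
  both <- dsc(e, e)
  expect_equal(as.double(both), 1)
  expect_true(attr(both, "both_empty"))
  expect_error(dsc(a, array(FALSE, c(2, 2, 2))), "shapes")
})

test_that("box IoU: closed forms and symmetry", {
  u <- box3(c(0, 0, 0), c(1, 1, 1))
  expect_equal(iou_boxes(u, u), 1)
  v <- box3(c(2, 2, 2), c(3, 3, 3))
  expect_equal(iou_boxes(u, v), 0)
  w <- box3(c(0.5, 0, 0), c(1.5, 1, 1))
  expect_equal(iou_boxes(u, w), 1 / 3)
  expect_equal(iou_boxes(u, w), iou_boxes(w, u))
  expect_error(box3(c(0, 0, 0), c(0, 1, 1)), "lo < hi")
})

test_that("bounding boxes come per connected component, largest first", {
  m <- array(FALSE, c(10, 10, 4))
  m[1:4, 1:4, 1:2] <- TRUE
  m[8:9, 8:9, 4] <- TRUE
  boxes <- mask_bounding_boxes(m)
  expect_length(boxes, 2)
  expect_equal(boxes[[1]]$lo, c(0, 0, 0))
  expect_equal(boxes[[1]]$hi, c(4, 4, 2))
  expect_equal(boxes[[2]]$lo, c(7, 7, 3))
  expect_length(mask_bounding_boxes(array(FALSE, c(3, 3, 3))), 0)
})

test_that("matching: paper threshold, single-match rule, degenerate cases", {
  truth <- box3(c(0, 0, 0), c(10, 10, 10))
  sliver <- detection(box3(c(9, 9, 9), c(12, 12, 12)), 0.9)
  expect_gte(iou_boxes(sliver$bbox, truth), 0.0001)
  m <- match_detections(list(sliver), list(truth), 0.01)
  got <- iou_boxes(sliver$bbox, truth)
  expect_equal(m$tp, as.integer(got >= 0.01))
  # a clear overlap of IoU ~ 0.02 is a TP at the 0.01 threshold
  p2 <- detection(box3(c(7, 0, 0), c(17, 3, 3)), 0.8)
  expect_lt(iou_boxes(p2$bbox, truth), 0.05)
  expect_gt(iou_boxes(p2$bbox, truth), 0.01)
  expect_equal(match_detections(list(p2), list(truth), 0.01)$tp, 1L)
  # two predictions on one truth: one TP, one FP
  twin <- list(detection(box3(c(0, 0, 0), c(10, 10, 10)), 0.9),
               detection(box3(c(1, 1, 1), c(9, 9, 9)), 0.8))
  m2 <- match_detections(twin, list(truth), 0.01)
  expect_equal(m2$tp, 1L)
  expect_equal(m2$fp, 1L)
  expect_equal(m2$fn, 0L)
  expect_error(match_detections(twin, list(truth), 0), "threshold")
})

test_that("greedy matching equals independent best-first enumeration", {
  set.seed(101)
  for (r in 1:60) {
    preds <- random_detections(sample(0:4, 1))
    truths <- random_boxes(sample(0:4, 1))
    m <- match_detections(preds, truths, 0.01)
    expect_equal(m$tp, brute_best_first(preds, truths, 0.01))
  }
})

test_that("average precision: hand case, oracle equality, rescale invariance", {
  b <- function(x) box3(c(x, 0, 0), c(x + 1, 1, 1))
  truths <- list(b(0), b(10))
  preds <- list(detection(b(0.1), 0.9), detection(b(5), 0.8),
                detection(b(10.2), 0.7))
  res <- average_precision(preds, truths, 0.01)
  expect_equal(res$ap, (1 + 2 / 3) / 2)
  # operating point at the lowest confidence: recall 1, precision 2/3
  res2 <- average_precision(preds, truths, 0.01, confidence_threshold = 0.7)
  expect_equal(res2$recall, 1)
  expect_equal(res2$precision, 2 / 3)
  # invariance under a monotone confidence rescale
  preds_r <- lapply(preds, function(p)
    detection(p$bbox, p$confidence^3))
  expect_equal(average_precision(preds_r, truths, 0.01)$ap, res$ap)
  # all predictions correct -> AP 1
  perfect <- list(detection(b(0), 0.3), detection(b(10), 0.6))
  expect_equal(average_precision(perfect, truths, 0.01)$ap, 1)
  expect_error(average_precision(preds, list(), 0.01), "zero ground-truth")
})

test_that("reader sensitivity: arithmetic, perfect reader, zero positives", {
  truth <- data.frame(image_id = sprintf("i%02d", 1:20),
                      value = c(rep("severe", 10), rep("none", 10)))
  reads <- data.frame(
    reader_id = "r1",
    image_id = truth$image_id,
    value = c(rep("mild", 8), rep("none", 2), rep("none", 10)))
  s <- sensitivity(reads, truth)
  expect_equal(unname(s$per_reader["r1"]), 0.8)
  expect_equal(s$mean, 0.8)
  perfect <- transform(reads, value = truth$value)
  expect_equal(sensitivity(perfect, truth)$mean, 1)
  none <- data.frame(image_id = truth$image_id, value = "none")
  s0 <- sensitivity(reads, none)
  expect_true(s0$undefined)
  expect_true(is.na(s0$mean))
})

test_that("Cohen's kappa: hand table, identity, independence, degeneracy", {
  x <- c(rep("a", 25), rep("b", 25))
  y <- c(rep("a", 20), rep("b", 5), rep("a", 10), rep("b", 15))
  expect_equal(cohens_kappa(x, y), 0.4)
  expect_equal(cohens_kappa(y, y), 1)
  set.seed(202)
  xi <- sample(c("p", "q"), 10000, TRUE)
  yi <- sample(c("p", "q"), 10000, TRUE)
  expect_lt(abs(cohens_kappa(xi, yi)), 0.05)
  k <- cohens_kappa(rep("a", 5), rep("a", 5))
  expect_equal(as.double(k), 1)
  expect_true(attr(k, "degenerate"))
  # ternary severity agreement stays in range
  sev <- c("none", "mild", "severe")
  expect_lte(cohens_kappa(sample(sev, 30, TRUE), sample(sev, 30, TRUE)), 1)
})

test_that("pearson: closed forms and validation", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  expect_equal(pearson(c(1, 2, 3), c(2, 2, 4)), sqrt(3) / 2, tolerance = 1e-3)
  expect_error(pearson(c(1, 2, 3), c(5, 5, 5)), "zero-variance")
  expect_error(pearson(1:2, 1:2), "length")
})
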