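classes2 <- c("background", "fg")

half_target <- function() {
  t <- array(0L, c(2, 2, 1))
  t[, 1, 1] <- 1L
  t
}

test_that("Dice loss: perfect, disjoint and hand-computed soft cases", {
  tg <- half_target()
  expect_equal(dice_loss(one_hot(tg, classes2, c(1, 1, 1)), tg), 0)
  wrong <- array(0, c(2, 2, 1, 2))
  wrong[, , , 2] <- as.double(tg == 0L)
  wrong[, , , 1] <- as.double(tg == 1L)
  expect_equal(dice_loss(soft_prediction(wrong, classes2, c(1, 1, 1)), tg), 1)
  half <- soft_prediction(array(0.5, c(2, 2, 1, 2)), classes2, c(1, 1, 1))
  # soft Dice = 2 * (0.5 * 2) / (2 + 2) = 0.5
  expect_equal(dice_loss(half, tg), 0.5)
})

test_that("focal loss: gamma = 0 is cross-entropy; hand value at p_t = 0.5", {
  tg <- half_target()
  half <- soft_prediction(array(0.5, c(2, 2, 1, 2)), classes2, c(1, 1, 1))
  expect_lt(abs(focal_loss(half, tg, 0) - (-log(0.5))), 1e-6)
  expect_equal(focal_loss(half, tg, 2), 0.25 * log(2))
  perfect <- one_hot(tg, classes2, c(1, 1, 1))
  expect_lt(focal_loss(perfect, tg, 2), 1e-10)
})

test_that("boundary loss matches a brute-force distance transform on 4x4x1", {
  tg <- array(0L, c(4, 4, 1))
  tg[, 1:2, 1] <- 1L
  oh <- one_hot(tg, classes2, c(1, 1, 1))
  # brute-force signed distances over all voxel pairs
  fg <- which(tg == 1L, arr.ind = TRUE)
  bg <- which(tg == 0L, arr.ind = TRUE)
  phi <- array(0, dim(tg))
  for (i in 1:4) for (j in 1:4) {
    p <- c(i, j, 1)
    dfg <- min(sqrt(colSums((t(fg) - p)^2)))
    dbg <- min(sqrt(colSums((t(bg) - p)^2)))
    phi[i, j, 1] <- if (tg[i, j, 1] == 1L) -dbg else dfg
  }
  expected <- mean(as.vector(oh$probs[, , , 2]) * as.vector(phi))
  expect_equal(boundary_loss(oh, tg, c(1, 1, 1)), expected)
  # all-background prediction puts no mass anywhere -> 0
  bgpred <- array(0, c(4, 4, 1, 2)); bgpred[, , , 1] <- 1
  expect_equal(boundary_loss(soft_prediction(bgpred, classes2, c(1, 1, 1)),
                             tg, c(1, 1, 1)), 0)
  # empty target is defined as 0 with a warning
  empty <- array(0L, c(4, 4, 1))
  expect_warning(val <- boundary_loss(oh, empty, c(1, 1, 1)), "empty")
  expect_equal(val, 0)
})

test_that("the true mask minimizes boundary loss among random predictions", {
  tg <- array(0L, c(4, 4, 1))
  tg[, 1:2, 1] <- 1L
  oh <- one_hot(tg, classes2, c(1, 1, 1))
  ref <- boundary_loss(oh, tg, c(1, 1, 1))
  set.seed(31)
  for (r in 1:100) {
    z <- array(rnorm(16), c(4, 4, 1))
    p <- 1 / (1 + exp(-z))
    pr <- array(0, c(4, 4, 1, 2))
    pr[, , , 2] <- p; pr[, , , 1] <- 1 - p
    expect_gt(boundary_loss(soft_prediction(pr, classes2, c(1, 1, 1)),
                            tg, c(1, 1, 1)), ref)
  }
})

test_that("combined loss decomposes and honors the focal:dice ratio", {
  tg <- half_target()
  half <- soft_prediction(array(0.5, c(2, 2, 1, 2)), classes2, c(1, 1, 1))
  cfg <- loss_config()
  expect_equal(combined_loss(half, tg, cfg),
               focal_loss(half, tg, 2) + dice_loss(half, tg))
  cfg2 <- loss_config(focal_dice_ratio = c(2, 1))
  expect_equal(combined_loss(half, tg, cfg2) - combined_loss(half, tg, cfg),
               focal_loss(half, tg, 2))
  perfect <- one_hot(tg, classes2, c(1, 1, 1))
  expect_lt(combined_loss(perfect, tg, cfg), 1e-9)
})

test_that("signed distance map uses physical spacing", {
  m <- array(FALSE, c(5, 5, 3))
  m[3, 3, 2] <- TRUE
  phi <- pelvamp:::signed_distance_mm(m, c(0.6, 0.6, 6.0))
  expect_equal(phi[4, 3, 2], 0.6)
  expect_equal(phi[3, 3, 1], 6.0)
  expect_equal(phi[3, 3, 2], -0.6) # nearest background one in-plane voxel away
})

test_that("ensemble mean averages members and preserves normalization", {
  set.seed(12)
  v <- volume(array(rnorm(6 * 6 * 2), c(6, 6, 2)), c(1, 1, 1))
  mk_model <- function(p1) function(vol) {
    out <- array(0, c(dim(vol$data), 2))
    out[, , , 2] <- p1; out[, , , 1] <- 1 - p1
    dimnames(out) <- c(rep(list(NULL), 3), list(classes2))
    out
  }
  e <- ensemble_predict(list(mk_model(0.2), mk_model(0.8)), v)
  expect_true(all(abs(e$probs[, , , 2] - 0.5) < 1e-12))
  # five identical members equal a single member
  one <- mk_model(0.3)
  e5 <- ensemble_predict(rep(list(one), 5), v)
  expect_equal(e5$probs, soft_prediction(one(v), classes2)$probs)
  # k random members equal the brute-force average
  set.seed(13)
  ps <- runif(4)
  models <- lapply(ps, mk_model)
  ek <- ensemble_predict(models, v)
  expect_equal(unique(as.vector(ek$probs[, , , 2])), mean(ps))
  tot <- apply(ek$probs, 1:3, sum)
  expect_lt(max(abs(tot - 1)), 1e-12)
})

test_that("trainer gradient matches finite differences (incl. boundary term)", {
  cfg <- loss_config(use_boundary = TRUE)
  set.seed(5)
  X <- cbind(1, matrix(rnorm(40 * 3), 40, 3))
  t <- sample(0:2, 40, TRUE)
  phi <- matrix(rnorm(40 * 2), 40, 2)
  W <- matrix(rnorm(4 * 3) * 0.1, 4, 3)
  lg <- pelvamp:::toy_loss_grad(X, t, W, cfg, phi)
  eps <- 1e-6
  for (idx in c(1, 5, 9, 12)) {
    Wp <- W; Wp[idx] <- Wp[idx] + eps
    Wm <- W; Wm[idx] <- Wm[idx] - eps
    num <- (pelvamp:::toy_loss_grad(X, t, Wp, cfg, phi)$loss -
              pelvamp:::toy_loss_grad(X, t, Wm, cfg, phi)$loss) / (2 * eps)
    expect_lt(abs(num - lg$grad[idx]), 1e-6)
  }
})

test_that("toy segmenter training decreases the loss and is reproducible", {
  coh <- generate_cohort(8, seed = 17, image_shape = c(48, 48, 10),
                         spacing_mm = c(2.4, 2.4, 12))
  m1 <- train_toy_segmenter(coh, loss_config(), epochs = 20, seed = 2)
  expect_lt(tail(m1$loss_history, 1), m1$loss_history[1])
  expect_true(all(diff(m1$loss_history) <= 1e-12))
  m2 <- train_toy_segmenter(coh, loss_config(), epochs = 20, seed = 2)
  expect_lt(abs(tail(m1$loss_history, 1) - tail(m2$loss_history, 1)), 1e-4)
  expect_warning(m0 <- train_toy_segmenter(coh, loss_config(), epochs = 0,
                                           seed = 2), "untrained")
  expect_length(m0$loss_history, 0)
  # predictor plugs into sliding-window inference
  pred <- sliding_window_predict(znormalize(coh[[1]]$t2_volume), m1$predict,
                                 patch_shape = c(48, 48, 10))
  expect_equal(dim(pred$probs)[4], 6L)
})
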