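# Toy pluggable segmentation backbone: a multiscale-feature softmax voxel
# classifier trained by full-batch gradient descent with backtracking line
# search on the combined focal + Dice (+ boundary) loss. It is deliberately
# NOT a deep network; it exists so the loss/ensembling/inference contracts
# can be exercised end-to-end at desk scale. The backbone is pluggable: any
# function patch -> per-class probabilities works with
# sliding_window_predict() and ensemble_predict().

seg_classes <- function() c("background", "uterus", "bladder", "rectum",
                            "ovary", "plaque")

# per-voxel features: bias, intensity, two Gaussian-smoothed scales, and
# normalized coordinates
voxel_features <- function(a) {
  d <- dim(a)
  s1 <- gaussian_smooth3d(a, c(1, 1, 0.5))
  s2 <- gaussian_smooth3d(a, c(3, 3, 1))
  co <- grid_coords(d, 2 / pmax(d - 1, 1)) - 1
  cbind(1, as.double(a), as.double(s1), as.double(s2), co)
}

# map an organ label mask to 0-based class indices (ovaries merged)
seg_target <- function(organ_mask) {
  classes <- seg_classes()
  lab <- organ_mask$data
  L <- organ_mask$labels
  idx <- array(0L, dim(lab))
  idx[lab == L[["uterus"]]] <- 1L
  idx[lab == L[["bladder"]]] <- 2L
  idx[lab == L[["rectum"]]] <- 3L
  idx[lab == L[["ovary_left"]] | lab == L[["ovary_right"]]] <- 4L
  idx[lab == L[["plaque"]]] <- 5L
  idx
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# loss and gradient (w.r.t. W) of the combined loss for one sample
toy_loss_grad <- function(X, t, W, cfg, phi = NULL) {
  N <- nrow(X)
  C <- ncol(W)
  P <- softmax_rows(X %*% W)
  t1 <- as.integer(t) + 1L
  pt <- pmin(pmax(P[cbind(seq_len(N), t1)], 1e-7), 1 - 1e-7)
  gam <- cfg$focal_gamma
  loss_f <- mean(-(1 - pt)^gam * log(pt))
  a <- (gam * (1 - pt)^(pmax(gam - 1, 0)) * log(pt) - (1 - pt)^gam / pt) / N
  Gz <- -a * pt * P
  Gz[cbind(seq_len(N), t1)] <- Gz[cbind(seq_len(N), t1)] + a * pt
  Gz <- cfg$focal_dice_ratio[1] * Gz

  # soft Dice over foreground classes
  fg <- 2:C
  dLdp <- matrix(0, N, C)
  dices <- numeric(length(fg))
  for (j in seq_along(fg)) {
    k <- fg[j]
    g <- as.double(t1 == k)
    I <- sum(P[, k] * g)
    den <- sum(P[, k]) + sum(g)
    dices[j] <- if (den == 0) 1 else 2 * I / den
    if (den > 0)
      dLdp[, k] <- -(2 * g * den - 2 * I) / den^2 / length(fg)
  }
  loss_d <- 1 - mean(dices)
  if (cfg$use_boundary && !is.null(phi)) {
    dLdp[, fg] <- dLdp[, fg] +
      cfg$boundary_weight * phi / (N * length(fg)) /
        cfg$focal_dice_ratio[2]
    # (phi columns already scaled below; see caller note)
  }
  S <- rowSums(dLdp * P)
  Gz <- Gz + cfg$focal_dice_ratio[2] * P * (dLdp - S)
  loss <- cfg$focal_dice_ratio[1] * loss_f + cfg$focal_dice_ratio[2] * loss_d
  if (cfg$use_boundary && !is.null(phi))
    loss <- loss + cfg$boundary_weight * sum(P[, fg, drop = FALSE] * phi) /
      (N * length(fg))
  list(loss = loss, grad = crossprod(X, Gz))
}

#' Train the toy segmenter
#'
#' Fits the pluggable desk-scale backbone (multiscale-feature softmax voxel
#' classifier) on a phantom cohort by full-batch gradient descent with
#' backtracking line search, which makes the recorded training loss
#' non-increasing by construction. Training diverging to NaN aborts with a
#' diagnostic.
#'
#' @param cohort list of `pv_phantom_sample` (at least 4).
#' @param cfg a [loss_config()].
#' @param epochs number of gradient epochs; `0` returns the untrained
#'   initialization with a warning.
#' @param seed integer controlling the random initialization.
#' @param lr initial learning rate.
#' @return A list of class `pv_toy_segmenter`: `predict(patch)` closure
#'   usable with [sliding_window_predict()], weight matrix `W`, `classes`,
#'   and the per-epoch `loss_history`.
#' @export
train_toy_segmenter <- function(cohort, cfg = loss_config(), epochs = 20,
                                seed = 1, lr = 5.0) {
  if (length(cohort) < 4) stopf("need a cohort of at least 4 samples")
  stopifnot(inherits(cfg, "pv_loss_config"))
  classes <- seg_classes()
  C <- length(classes)
  data <- lapply(cohort, function(s) {
    v <- znormalize(s$t2_volume)
    X <- voxel_features(v$data)
    t <- as.integer(seg_target(s$organ_mask))
    phi <- NULL
    if (cfg$use_boundary) {
      phi <- sapply(2:C, function(k) {
        g <- array(t == (k - 1L), dim(v$data))
        if (!any(g)) rep(0, length(t))
        else as.double(signed_distance_mm(g, s$t2_volume$spacing_mm))
      })
    }
    list(X = X, t = t, phi = phi)
  })
  W <- with_seed(seed, function()
    matrix(rnorm(ncol(data[[1]]$X) * C, 0, 0.01), ncol = C))
  history <- numeric(0)
  total <- function(W) {
    l <- 0; G <- matrix(0, nrow(W), ncol(W))
    for (s in data) {
      lg <- toy_loss_grad(s$X, s$t, W, cfg, s$phi)
      l <- l + lg$loss / length(data)
      G <- G + lg$grad / length(data)
    }
    list(loss = l, grad = G)
  }
  if (epochs == 0) {
    warnf("epochs = 0: returning the untrained initialization")
  } else {
    cur <- total(W)
    for (ep in seq_len(epochs)) {
      if (!is.finite(cur$loss))
        stopf("training diverged (non-finite loss) at epoch %d", ep)
      ok <- FALSE
      for (try in 1:30) {
        W2 <- W - lr * cur$grad
        nxt <- total(W2)
        if (is.finite(nxt$loss) && nxt$loss <= cur$loss) {
          W <- W2; cur <- nxt; lr <- lr * 1.2; ok <- TRUE
          break
        }
        lr <- lr / 2
      }
      if (!ok) { # converged: no descent step found
        history <- c(history, cur$loss)
        next
      }
      history <- c(history, cur$loss)
    }
  }
  predictor <- local({
    W_ <- W; cls <- classes
    function(patch) {
      a <- if (inherits(patch, "pv_volume")) patch$data else patch
      X <- voxel_features(a)
      P <- softmax_rows(X %*% W_)
      out <- array(P, c(dim(a), length(cls)))
      dimnames(out) <- c(rep(list(NULL), 3), list(cls))
      out
    }
  })
  structure(list(predict = predictor, W = W, classes = classes,
                 loss_history = history, config = cfg, seed = seed),
            class = "pv_toy_segmenter")
}

#' Predict a full volume with a trained toy segmenter
#'
#' @param model a `pv_toy_segmenter`.
#' @param v `pv_volume` (z-normalized internally).
#' @return `pv_soft_prediction`.
#' @export
predict_segmentation <- function(model, v) {
  stopifnot(inherits(model, "pv_toy_segmenter"))
  probs <- model$predict(znormalize(v)$data)
  soft_prediction(probs, model$classes, v$spacing_mm)
}
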