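label_col <- function(location) paste0("label__", location)

#' Assemble an adhesion dataset
#'
#' Rows are MR images; columns are the 56 shape features, seven binary
#' adhesion labels (one per location) and a patient identifier used for
#' grouped cross-validation.
#'
#' @param features numeric matrix/data.frame with the 56 `organ__feature`
#'   columns (one row per image).
#' @param labels data.frame/matrix of 7 binary columns ordered as
#'   [adhesion_locations()].
#' @param patient_id character vector, one per row.
#' @param image_id optional image identifiers (default sequential).
#' @return A data.frame of class `pv_adhesion_dataset`.
#' @export
adhesion_dataset <- function(features, labels, patient_id, image_id = NULL) {
  features <- as.data.frame(features)
  labels <- as.data.frame(labels)
  if (ncol(labels) != 7L) stopf("`labels` must have 7 columns")
  names(labels) <- label_col(adhesion_locations())
  if (!all(unlist(labels) %in% c(0, 1)))
    stopf("labels must be binary 0/1")
  n <- nrow(features)
  if (nrow(labels) != n || length(patient_id) != n)
    stopf("features, labels and patient_id disagree on row count")
  image_id <- image_id %||% sprintf("img%04d", seq_len(n))
  if (anyDuplicated(paste(patient_id, image_id)))
    stopf("duplicate (patient, image) keys")
  ds <- cbind(data.frame(patient_id = as.character(patient_id),
                         image_id = as.character(image_id),
                         stringsAsFactors = FALSE),
              features, labels)
  class(ds) <- c("pv_adhesion_dataset", "data.frame")
  ds
}

#' Adhesion dataset from a phantom cohort
#'
#' Extracts the 56-dim feature vector of every sample's organ mask and pairs
#' it with the cohort's ground-truth adhesion labels.
#'
#' @param cohort list of `pv_phantom_sample` (from [generate_cohort()]).
#' @return A `pv_adhesion_dataset`.
#' @export
cohort_adhesion_dataset <- function(cohort) {
  feats <- t(vapply(cohort, function(s) as.numeric(feature_vector(s$organ_mask)),
                    numeric(56)))
  colnames(feats) <- names(feature_vector(cohort[[1]]$organ_mask))
  labs <- t(vapply(cohort, function(s) as.integer(s$truth$adhesion),
                   integer(7)))
  adhesion_dataset(feats, labs,
                   patient_id = vapply(cohort, `[[`, "", "patient_id"),
                   image_id = vapply(cohort, function(s)
                     s$image_id %||% s$patient_id, ""))
}

feature_cols <- function(ds) setdiff(names(ds),
                                     c("patient_id", "image_id",
                                       label_col(adhesion_locations())))

# per-patient binary label for one location (max over the patient's images)
patient_labels <- function(ds, location) {
  lc <- label_col(location)
  tapply(ds[[lc]], ds$patient_id, max)
}

#' Patient-grouped stratified fold assignment
#'
#' Every image of a patient lands in the same fold; folds are balanced by
#' assigning positive and negative patients round-robin after a seeded
#' shuffle. When stratification is impossible (all patients one class) the
#' assignment degrades to grouped-only with a warning.
#'
#' @param ds a `pv_adhesion_dataset`.
#' @param k number of folds (default 5).
#' @param location one of [adhesion_locations()].
#' @param seed integer.
#' @return Integer fold id (1..k) per dataset row.
#' @export
grouped_stratified_folds <- function(ds, k = 5, location = "uterus-rectum",
                                     seed = 1) {
  stopifnot(inherits(ds, "pv_adhesion_dataset"))
  if (!location %in% adhesion_locations()) stopf("unknown location '%s'", location)
  plab <- patient_labels(ds, location)
  patients <- names(plab)
  if (length(patients) < k)
    stopf("need at least %d patients for %d folds", k, k)
  with_seed(seed, function() {
    if (length(unique(plab)) < 2) {
      warnf("stratification impossible (single class); using grouped-only folds")
      ord <- sample(patients)
      fold_of <- setNames(rep_len(seq_len(k), length(ord)), ord)
    } else {
      fold_of <- c()
      for (cls in c(1, 0)) {
        ord <- sample(patients[plab == cls])
        fold_of <- c(fold_of, setNames(rep_len(seq_len(k), length(ord)), ord))
      }
    }
    as.integer(fold_of[ds$patient_id])
  })
}

impute_medians <- function(X, medians = NULL) {
  medians <- medians %||% apply(X, 2, function(col) {
    m <- stats::median(col, na.rm = TRUE)
    if (is.na(m)) 0 else m
  })
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- medians[j]
  }
  list(X = X, medians = medians)
}

#' Train a per-location adhesion classifier
#'
#' Gradient-boosted decision trees (binary logistic objective) on the 56-dim
#' shape feature vectors. Small-data-safe defaults: 200 trees, depth 4,
#' learning rate 0.1, no early stopping. Missing features (absent organs)
#' are imputed with training-set medians stored in the model.
#'
#' @param ds a `pv_adhesion_dataset`.
#' @param location one of [adhesion_locations()].
#' @param hyperparams optional list overriding `nrounds`, `max_depth`,
#'   `eta`.
#' @param seed integer.
#' @return A list of class `pv_adhesion_model`.
#' @export
train_adhesion <- function(ds, location = "uterus-rectum",
                           hyperparams = list(), seed = 1) {
  stopifnot(inherits(ds, "pv_adhesion_dataset"))
  y <- ds[[label_col(location)]]
  if (length(unique(y)) < 2)
    stopf("training data for '%s' contains a single class", location)
  hp <- utils::modifyList(list(nrounds = 200, max_depth = 4, eta = 0.1),
                          hyperparams)
  X <- as.matrix(ds[, feature_cols(ds), drop = FALSE])
  imp <- impute_medians(X)
  dtrain <- xgboost::xgb.DMatrix(imp$X, label = as.numeric(y), nthread = 1)
  booster <- with_seed(seed, function()
    xgboost::xgb.train(params = list(objective = "binary:logistic",
                                     max_depth = hp$max_depth, eta = hp$eta,
                                     nthread = 1, seed = seed),
                       data = dtrain, nrounds = hp$nrounds, verbose = 0))
  structure(list(booster = booster, medians = imp$medians,
                 feature_names = feature_cols(ds), location = location,
                 hyperparams = hp, seed = seed),
            class = "pv_adhesion_model")
}

#' @export
predict.pv_adhesion_model <- function(object, newdata, ...) {
  nf <- length(object$feature_names)
  X <- if (is.data.frame(newdata)) {
    as.matrix(newdata[, object$feature_names, drop = FALSE])
  } else {
    if (length(newdata) %% nf != 0)
      stopf("feature length mismatch: got %d, expected a multiple of %d",
            length(newdata), nf)
    matrix(newdata, ncol = nf, byrow = TRUE,
           dimnames = list(NULL, object$feature_names))
  }
  X <- impute_medians(X, object$medians)$X
  stats::predict(object$booster, xgboost::xgb.DMatrix(X, nthread = 1))
}

binary_metrics <- function(y, call) {
  tp <- sum(y == 1 & call == 1)
  fp <- sum(y == 0 & call == 1)
  fn <- sum(y == 1 & call == 0)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision_defined <- (tp + fp) > 0
  precision <- if (precision_defined) tp / (tp + fp) else 0
  f1 <- if (!is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else 0
  list(recall = recall, precision = precision, f1 = f1,
       precision_defined = precision_defined)
}

#' Cross-validated adhesion metrics
#'
#' Patient-grouped stratified k-fold cross-validation; out-of-fold
#' probabilities are pooled, thresholded at 0.5 and summarized as recall,
#' precision and F1 with 95% percentile-bootstrap confidence intervals
#' (2000 resamples of the pooled predictions). An all-negative predictor
#' yields precision 0 with `precision_defined = FALSE`.
#'
#' @inheritParams train_adhesion
#' @param k folds (default 5).
#' @param threshold decision threshold on the predicted probability.
#' @param n_boot bootstrap resamples for the CIs.
#' @return A list of class `pv_cv_metrics`.
#' @export
evaluate_cv <- function(ds, location = "uterus-rectum", k = 5, seed = 1,
                        hyperparams = list(), threshold = 0.5,
                        n_boot = 2000) {
  stopifnot(inherits(ds, "pv_adhesion_dataset"))
  folds <- grouped_stratified_folds(ds, k, location, seed)
  y <- ds[[label_col(location)]]
  prob <- rep(NA_real_, nrow(ds))
  for (f in seq_len(k)) {
    tr <- folds != f
    if (!any(tr) || !any(!tr)) next
    model <- train_adhesion(ds[tr, , drop = FALSE], location, hyperparams,
                            seed = seed + f)
    prob[!tr] <- predict(model, ds[!tr, , drop = FALSE])
  }
  call <- as.integer(prob >= threshold)
  point <- binary_metrics(y, call)
  ci <- if (n_boot > 0) with_seed(seed, function() {
    n <- length(y)
    reps <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      m <- binary_metrics(y[i], call[i])
      c(m$recall, m$precision, m$f1)
    }, numeric(3))
    apply(reps, 1, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  }) else matrix(NA_real_, 2, 3)
  structure(list(location = location,
                 recall = point$recall, precision = point$precision,
                 f1 = point$f1,
                 recall_ci = ci[, 1], precision_ci = ci[, 2], f1_ci = ci[, 3],
                 precision_defined = point$precision_defined,
                 n_positive = sum(patient_labels(ds, location) == 1),
                 oof_prob = prob, folds = folds),
            class = "pv_cv_metrics")
}

#' @export
print.pv_cv_metrics <- function(x, ...) {
  cat(sprintf("<cv metrics> %s: recall %.2f (%.2f-%.2f), precision %.2f (%.2f-%.2f), F1 %.2f (%.2f-%.2f), n+ %d\n",
              x$location, x$recall, x$recall_ci[1], x$recall_ci[2],
              x$precision, x$precision_ci[1], x$precision_ci[2],
              x$f1, x$f1_ci[1], x$f1_ci[2], x$n_positive))
  invisible(x)
}

#' Permutation null distribution of the cross-validated F1
#'
#' Shuffles patient-level labels across patients (images keep their
#' patient's permuted label, preserving the grouping structure) and re-runs
#' the full cross-validation, giving the chance-level F1 distribution.
#'
#' @inheritParams evaluate_cv
#' @param n_perm number of label shuffles.
#' @return Numeric vector of null F1 values.
#' @export
permutation_null_f1 <- function(ds, location = "uterus-rectum", n_perm = 100,
                                k = 5, seed = 1, hyperparams = list()) {
  plab <- patient_labels(ds, location)
  patients <- names(plab)
  lc <- label_col(location)
  with_seed(seed, function() {
    vapply(seq_len(n_perm), function(p) {
      perm <- setNames(sample(plab), patients)
      ds2 <- ds
      ds2[[lc]] <- as.integer(perm[ds$patient_id])
      if (length(unique(ds2[[lc]])) < 2) return(NA_real_)
      res <- suppressWarnings(
        evaluate_cv(ds2, location, k = k, seed = seed + p,
                    hyperparams = hyperparams, n_boot = 0))
      res$f1
    }, numeric(1))
  })
}

#' Predict all seven adhesion locations for one feature vector
#'
#' @param classifiers named list of 7 `pv_adhesion_model`s keyed by
#'   location.
#' @param fv 56-dim feature vector (from [feature_vector()]).
#' @param threshold decision threshold.
#' @return Data.frame with `location`, `probability`, `call`, ordered as
#'   [adhesion_locations()].
#' @export
predict_adhesions <- function(classifiers, fv, threshold = 0.5) {
  locs <- adhesion_locations()
  if (!all(locs %in% names(classifiers)))
    stopf("`classifiers` must contain all 7 locations")
  probs <- vapply(locs, function(l)
    as.numeric(predict(classifiers[[l]], matrix(as.numeric(fv), nrow = 1))),
    numeric(1))
  data.frame(location = locs, probability = probs,
             call = as.integer(probs >= threshold),
             row.names = NULL, stringsAsFactors = FALSE)
}
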