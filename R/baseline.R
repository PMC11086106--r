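#' Train the gradient-boosted baseline
#'
#' Extreme gradient boosting on the 53 engineered features, the comparison
#' arm for the convolutional model. Binary logistic objective; prediction
#' yields a preictal probability in \[0, 1\].
#'
#' @param features numeric matrix or data.frame of feature columns
#'   (provenance columns, if present, are dropped).
#' @param labels binary vector (1 = preictal).
#' @param nrounds boosting rounds (default 60).
#' @param max_depth tree depth (default 3).
#' @param eta learning rate (default 0.3).
#' @param seed integer seed.
#' @return An object of class `seiz_baseline` wrapping the booster.
#' @export
train_baseline <- function(features, labels, nrounds = 60, max_depth = 3,
                           eta = 0.3, seed = 1) {
  X <- .feature_matrix(features)
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2)
    stop("training labels contain a single class; cannot fit a classifier")
  dtrain <- xgboost::xgb.DMatrix(X, label = labels)
  bst <- withr::with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1),
    data = dtrain, nrounds = nrounds, verbose = 0))
  structure(list(booster = bst, n_features = ncol(X),
                 feature_names = colnames(X), nrounds = nrounds,
                 max_depth = max_depth, eta = eta),
            class = "seiz_baseline")
}

#' Calibrate the baseline on target-patient seizures
#'
#' Continued boosting: additional trees are fitted to the calibration
#' windows starting from the patient-independent ensemble, whose trees are
#' left untouched — the tree-model analogue of warm-start fine-tuning. (Full
#' retraining on pooled data is available via `mode = "retrain"`.)
#'
#' @param model a trained `seiz_baseline`.
#' @param cal_features,cal_labels calibration windows' features and labels.
#' @param extra_rounds additional boosting rounds (default 20).
#' @param mode "continue" (default) or "retrain".
#' @param seed integer seed.
#' @return A calibrated `seiz_baseline`; the input model is not modified.
#' @export
calibrate_baseline <- function(model, cal_features, cal_labels,
                               extra_rounds = 20, mode = c("continue", "retrain"),
                               seed = 1) {
  mode <- match.arg(mode)
  X <- .feature_matrix(cal_features)
  if (ncol(X) != model$n_features)
    stop("calibration features have ", ncol(X), " columns; model expects ",
         model$n_features)
  if (mode == "retrain")
    return(train_baseline(X, cal_labels, nrounds = model$nrounds + extra_rounds,
                          max_depth = model$max_depth, eta = model$eta,
                          seed = seed))
  dcal <- xgboost::xgb.DMatrix(X, label = as.numeric(cal_labels))
  # min_child_weight 0: when the source ensemble is already confident the
  # logistic hessians on calibration points are tiny and the default
  # pruning threshold would reject every split, freezing the continuation
  bst <- withr::with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = model$max_depth,
                  eta = model$eta, min_child_weight = 0, nthread = 1),
    data = dcal, nrounds = extra_rounds, verbose = 0,
    xgb_model = model$booster))
  model$booster <- bst
  model
}

#' Predict preictal probabilities with the baseline
#'
#' @param object a `seiz_baseline`.
#' @param newdata feature matrix/data.frame.
#' @param ... unused.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict.seiz_baseline <- function(object, newdata, ...) {
  X <- .feature_matrix(newdata)
  if (ncol(X) != object$n_features)
    stop("feature count mismatch: got ", ncol(X), ", model expects ",
         object$n_features)
  as.numeric(stats::predict(object$booster, xgboost::xgb.DMatrix(X)))
}

.feature_matrix <- function(features) {
  if (is.data.frame(features))
    features <- features[setdiff(colnames(features),
                                 c("label", "patient_id", "seizure_index"))]
  as.matrix(features)
}
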