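# Activity-class gate: k-nearest-neighbour classifier with squared-inverse
# distance weighting, plus leave-one-subject-out evaluation.

#' Fit the k-nearest-neighbour activity-class gate
#'
#' Stores the (optionally standardised) training points and labels. Distances
#' are Euclidean on the selected features; by default each feature is
#' standardised with the training rows' mean and SD, since the features mix
#' wildly different units.
#'
#' @param x feature matrix or [assemble_feature_table()] output (label
#'   columns are ignored).
#' @param labels activity-class labels, one per row.
#' @param k number of neighbours (default 10).
#' @param features feature names to use (default: the published five-feature
#'   gate, see [feature_preset()]`("classifier")`).
#' @param standardize standardise features with training statistics (default
#'   TRUE).
#' @return an object of class `knn_gate`.
#' @export
knn_gate <- function(x, labels, k = 10, features = feature_preset("classifier")$features,
                     standardize = TRUE) {
  X <- extract_feature_matrix(x, features)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(X))
  if (anyNA(X)) stop_iscee("missing values in selected features", "iscee_data_error")
  if (nrow(X) < k) stop_iscee(sprintf("need at least k = %d training rows", k),
                              "iscee_data_error")
  if (k < 1) stop_iscee("k must be >= 1", "iscee_config_error")
  center <- if (standardize) colMeans(X) else rep(0, ncol(X))
  scale_ <- if (standardize) apply(X, 2, sd) else rep(1, ncol(X))
  scale_[scale_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  structure(list(k = as.integer(k), features = features,
                 standardize = standardize, center = center, scale = scale_,
                 train = Xs, labels = labels,
                 classes = ACTIVITY_CLASSES),
            class = "knn_gate")
}

extract_feature_matrix <- function(x, features) {
  if (is.data.frame(x)) {
    missing <- setdiff(features, names(x))
    if (length(missing)) {
      stop_iscee(paste("feature(s) not in table:", paste(missing, collapse = ", ")),
                 "iscee_config_error")
    }
    x <- as.matrix(x[, features, drop = FALSE])
  } else {
    x <- as.matrix(x)
    if (!is.null(colnames(x))) x <- x[, features, drop = FALSE]
  }
  storage.mode(x) <- "double"
  x
}

#' @export
print.knn_gate <- function(x, ...) {
  cat(sprintf("<knn_gate> k = %d, %d training rows, features: %s\n",
              x$k, nrow(x$train), paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Classify windows with a fitted gate
#'
#' For each query row the `k` nearest training rows vote with weight
#' `1/d^2`; the predicted class maximises the summed weight. Exact matches
#' (`d = 0`) decide by majority among themselves. Ties break deterministically
#' in the fixed class order sedentary < low_intensity < high_intensity <
#' walking.
#'
#' @param object a fitted [knn_gate()].
#' @param newdata feature matrix or feature table.
#' @param ... unused.
#' @return character vector of predicted classes, with the per-class weight
#'   shares in attribute `"shares"`.
#' @export
predict.knn_gate <- function(object, newdata, ...) {
  Q <- extract_feature_matrix(newdata, object$features)
  if (anyNA(Q)) stop_iscee("missing values in selected features", "iscee_data_error")
  Q <- sweep(sweep(Q, 2, object$center), 2, object$scale, "/")
  classes <- object$classes
  train <- object$train
  tl <- object$labels
  out <- character(nrow(Q))
  shares <- matrix(0, nrow(Q), length(classes), dimnames = list(NULL, classes))
  for (i in seq_len(nrow(Q))) {
    d2 <- colSums((t(train) - Q[i, ])^2)
    ord <- order(d2)[seq_len(object$k)]
    dk <- d2[ord]
    lk <- tl[ord]
    if (any(dk == 0)) {
      votes <- table(factor(lk[dk == 0], levels = classes))
    } else {
      w <- 1 / dk
      votes <- vapply(classes, function(cl) sum(w[lk == cl]), 0)
    }
    votes <- as.numeric(votes)
    shares[i, ] <- if (sum(votes) > 0) votes / sum(votes) else 0
    out[i] <- classes[which.max(votes)]  # which.max: first max = fixed order
  }
  attr(out, "shares") <- shares
  out
}

#' Confusion report of a classification
#'
#' @param truth,predicted class labels.
#' @return list of class `confusion_report` with the 4x4 count matrix (rows =
#'   truth), overall accuracy and per-class sensitivity.
#' @export
confusion_report <- function(truth, predicted) {
  m <- table(factor(truth, levels = ACTIVITY_CLASSES),
             factor(predicted, levels = ACTIVITY_CLASSES))
  acc <- sum(diag(m)) / sum(m)
  sens <- diag(m) / rowSums(m)
  structure(list(matrix = unclass(m), accuracy = acc, sensitivity = sens),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("<confusion_report> accuracy %.1f%% (n = %d)\n",
              100 * x$accuracy, sum(x$matrix)))
  print(x$matrix)
  invisible(x)
}

#' Leave-one-subject-out evaluation of the activity-class gate
#'
#' One fold per subject: the held-out subject's windows are predicted by a
#' gate trained on all other subjects, and the per-fold predictions are
#' pooled into one confusion report.
#'
#' @param features a feature table from [assemble_feature_table()] (must
#'   contain `subject_id` and `activity_class` columns).
#' @param k,feature_set,standardize passed to [knn_gate()].
#' @return a [confusion_report()] with per-window predictions in attribute
#'   `"predicted"`.
#' @export
loso_classify <- function(features, k = 10,
                          feature_set = feature_preset("classifier")$features,
                          standardize = TRUE) {
  subjects <- unique(features$subject_id)
  if (length(subjects) < 2) stop_iscee("need >= 2 subjects for LOSO",
                                       "iscee_data_error")
  pred <- character(nrow(features))
  for (s in subjects) {
    test <- features$subject_id == s
    if (!any(test)) { warning(sprintf("subject %s has no windows", s)); next }
    fit <- knn_gate(features[!test, , drop = FALSE],
                    features$activity_class[!test], k = k,
                    features = feature_set, standardize = standardize)
    pred[test] <- as.character(predict(fit, features[test, , drop = FALSE]))
  }
  rep <- confusion_report(features$activity_class, pred)
  attr(rep, "predicted") <- pred
  rep
}
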