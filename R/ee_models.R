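# EE regression models: multiple linear regression fitted by minimising the
# sum of squared relative errors, a Levenberg-Marquardt-trained ensemble of
# single-hidden-layer sigmoid networks, and the direct / class-conditional
# model bundles that tie them to the activity-class gate.

#' Relative-error multiple linear regression
#'
#' Fits `EE = b0 + sum(bi * Fi)` by minimising the sum of squared *relative*
#' errors, `sum(((fitted - y) / y)^2)`. Because each residual is scaled by
#' its own positive target, the minimiser has an exact closed form: weighted
#' least squares with weights `1/y^2`.
#'
#' @param x feature matrix or feature table (label columns ignored).
#' @param y positive response (EE in kcal/day).
#' @param features feature names to use (default: all columns of `x`).
#' @return an object of class `relmlr` with `coef`, `predict`, `residuals`,
#'   `fitted`, `print` and `summary` methods.
#' @export
relmlr <- function(x, y, features = NULL) {
  if (is.null(features)) {
    features <- if (is.data.frame(x)) setdiff(names(x), META_COLUMNS) else colnames(x)
  }
  X <- extract_feature_matrix(x, features)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X))
  if (anyNA(X)) stop_iscee("missing values in selected features", "iscee_data_error")
  if (any(y <= 0)) stop_iscee("all responses must be > 0 for relative-error fitting",
                              "iscee_data_error")
  if (nrow(X) < ncol(X) + 1) {
    stop_iscee("need at least one more row than features", "iscee_data_error")
  }
  D <- cbind(`(Intercept)` = 1, X)
  qrD <- qr(D * (1 / y))  # rank check on the weighted design
  if (qrD$rank < ncol(D)) {
    dep <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stop_iscee(paste("design is rank deficient; collinear feature(s):",
                     paste(dep, collapse = ", ")), "iscee_data_error")
  }
  fit <- lm.wfit(D, y, w = 1 / y^2)
  beta <- fit$coefficients
  fitted <- as.numeric(D %*% beta)
  structure(list(coefficients = beta, features = features, fitted = fitted,
                 y = y, objective = sum(((fitted - y) / y)^2), n = length(y)),
            class = "relmlr")
}

#' @export
coef.relmlr <- function(object, ...) object$coefficients

#' @export
fitted.relmlr <- function(object, ...) object$fitted

#' @export
residuals.relmlr <- function(object, type = c("relative", "response"), ...) {
  type <- match.arg(type)
  r <- object$fitted - object$y
  if (type == "relative") r / object$y else r
}

#' Predict EE from a fitted relative-error regression
#'
#' Affine evaluation of the fitted coefficients; predictions are not clipped
#' (negative values are possible and reported as-is).
#'
#' @param object a [relmlr()] fit.
#' @param newdata feature matrix or feature table carrying the model's
#'   features.
#' @param ... unused.
#' @return numeric vector of EE estimates in kcal/day.
#' @export
predict.relmlr <- function(object, newdata, ...) {
  X <- extract_feature_matrix(newdata, object$features)
  if (anyNA(X)) stop_iscee("missing values in selected features", "iscee_data_error")
  as.numeric(cbind(1, X) %*% object$coefficients)
}

#' @export
print.relmlr <- function(x, ...) {
  cat(sprintf("<relmlr> %d features, n = %d, relative SSE = %.4g\n",
              length(x$features), x$n, x$objective))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.relmlr <- function(object, ...) {
  r <- residuals(object)
  cat(sprintf("Relative-error linear model (n = %d)\n", object$n))
  cat(sprintf("  objective sum((r/y)^2): %.6g\n", object$objective))
  cat(sprintf("  MAE %%: %.2f, mean signed %%: %.2f, max %%: %.2f\n",
              100 * mean(abs(r)), 100 * mean(r), 100 * max(abs(r))))
  invisible(object)
}

## ---- neural-network ensemble ----------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

# Nguyen-Widrow initialisation for one hidden layer on inputs scaled to
# [-1, 1]: hidden weight rows are normalised to magnitude 0.7 * H^(1/n_in)
# with evenly spaced biases; output layer small uniform.
nguyen_widrow_init <- function(n_in, hidden) {
  beta <- 0.7 * hidden^(1 / n_in)
  W <- matrix(runif(hidden * n_in, -0.5, 0.5), hidden, n_in)
  norms <- sqrt(rowSums(W^2))
  W <- W * beta / norms
  b <- beta * seq(-1, 1, length.out = hidden) * sign(W[, 1])
  v <- runif(hidden, -0.5, 0.5)
  list(W = W, b = b, v = v, b2 = runif(1, -0.5, 0.5))
}

pack_net <- function(net) c(as.numeric(net$W), net$b, net$v, net$b2)
unpack_net <- function(theta, n_in, hidden) {
  W <- matrix(theta[seq_len(hidden * n_in)], hidden, n_in)
  off <- hidden * n_in
  list(W = W, b = theta[off + seq_len(hidden)],
       v = theta[off + hidden + seq_len(hidden)], b2 = theta[off + 2 * hidden + 1])
}

net_forward <- function(theta, X, n_in, hidden) {
  net <- unpack_net(theta, n_in, hidden)
  A <- sigmoid(sweep(X %*% t(net$W), 2, net$b, "+"))
  list(yhat = as.numeric(A %*% net$v + net$b2), A = A, net = net)
}

# Residual Jacobian of yhat w.r.t. packed parameters (analytic).
net_jacobian <- function(fw, X, hidden) {
  A <- fw$A; v <- fw$net$v
  n <- nrow(X); n_in <- ncol(X)
  dA <- A * (1 - A)                      # n x hidden
  JW <- matrix(0, n, hidden * n_in)
  for (j in seq_len(n_in)) {
    JW[, (j - 1) * hidden + seq_len(hidden)] <- dA * X[, j] *
      matrix(v, n, hidden, byrow = TRUE)
  }
  cbind(JW, dA * matrix(v, n, hidden, byrow = TRUE), A, rep(1, n))
}

train_one_net <- function(X, y, hidden, max_epochs, gradient_tol,
                          val_fail_limit, train_frac) {
  n <- nrow(X); n_in <- ncol(X)
  idx <- sample.int(n)
  n_tr <- max(2, round(train_frac * n))
  tr <- idx[seq_len(n_tr)]; va <- idx[-seq_len(n_tr)]
  if (!length(va)) va <- tr
  theta <- pack_net(nguyen_widrow_init(n_in, hidden))
  lambda <- 1e-2
  best <- list(theta = theta, val = Inf)
  fails <- 0
  Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
  Xva <- X[va, , drop = FALSE]; yva <- y[va]
  fw <- net_forward(theta, Xtr, n_in, hidden)
  err <- fw$yhat - ytr
  sse <- sum(err^2)
  for (epoch in seq_len(max_epochs)) {
    J <- net_jacobian(fw, Xtr, hidden)
    g <- 2 * crossprod(J, err)
    if (max(abs(g)) < gradient_tol) break
    JtJ <- crossprod(J)
    repeat {
      delta <- tryCatch(solve(JtJ + lambda * diag(ncol(JtJ)), -crossprod(J, err)),
                        error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      cand <- theta + as.numeric(delta)
      fw2 <- net_forward(cand, Xtr, n_in, hidden)
      err2 <- fw2$yhat - ytr
      sse2 <- sum(err2^2)
      if (sse2 < sse || lambda > 1e10) {
        theta <- cand; fw <- fw2; err <- err2; sse <- sse2
        lambda <- max(lambda / 10, 1e-12)
        break
      }
      lambda <- lambda * 10
    }
    val <- sum((net_forward(theta, Xva, n_in, hidden)$yhat - yva)^2)
    if (val < best$val) {
      best <- list(theta = theta, val = val)
      fails <- 0
    } else {
      fails <- fails + 1
      if (fails >= val_fail_limit) break
    }
  }
  best$theta
}

#' Fit an ensemble of single-hidden-layer sigmoid networks
#'
#' Each member network is trained on standardised inputs and targets by
#' Levenberg-Marquardt minimisation of the sum of squared errors, starting
#' from Nguyen-Widrow initial weights, on a fresh random 70/30
#' training/validation split. Training stops at `max_epochs`, when the error
#' gradient drops below `gradient_tol`, or when the validation error
#' increases `val_fail_limit` times in a row (the best-validation weights are
#' kept). The ensemble prediction is the mean over member networks; results
#' are fully reproducible given `seed`.
#'
#' @param x feature matrix or feature table.
#' @param y response (EE in kcal/day), positive.
#' @param features feature names (default: all columns).
#' @param hidden_units hidden-layer size (the shipped presets use 3 for the
#'   class-conditional models and 6 for the direct model).
#' @param ensemble_size number of member networks (default 100; reduce for
#'   quick runs).
#' @param max_epochs,gradient_tol,val_fail_limit,train_frac training controls
#'   (defaults 500, 1e-6, 6, 0.7).
#' @param seed master seed; fans out one seed per member network.
#' @return an object of class `ann_ensemble`.
#' @export
ann_ensemble <- function(x, y, features = NULL, hidden_units = 3,
                         ensemble_size = 100, max_epochs = 500,
                         gradient_tol = 1e-6, val_fail_limit = 6,
                         train_frac = 0.7, seed = 1) {
  if (is.null(features)) {
    features <- if (is.data.frame(x)) setdiff(names(x), META_COLUMNS) else colnames(x)
  }
  X <- extract_feature_matrix(x, features)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), ensemble_size >= 1)
  if (any(y <= 0)) stop_iscee("responses must be > 0", "iscee_data_error")
  x_center <- colMeans(X); x_scale <- apply(X, 2, sd); x_scale[x_scale == 0] <- 1
  y_center <- mean(y); y_scale <- sd(y); if (y_scale == 0) y_scale <- 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  ys <- (y - y_center) / y_scale
  seeds <- seed + seq_len(ensemble_size) - 1L
  nets <- lapply(seeds, function(s) {
    set.seed(s %% .Machine$integer.max)
    train_one_net(Xs, ys, hidden_units, max_epochs, gradient_tol,
                  val_fail_limit, train_frac)
  })
  structure(list(features = features, hidden_units = as.integer(hidden_units),
                 nets = nets, x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale, seed = seed,
                 ensemble_size = as.integer(ensemble_size)),
            class = "ann_ensemble")
}

#' @export
predict.ann_ensemble <- function(object, newdata, ...) {
  X <- extract_feature_matrix(newdata, object$features)
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  n_in <- ncol(Xs)
  preds <- vapply(object$nets, function(th) {
    net_forward(th, Xs, n_in, object$hidden_units)$yhat
  }, numeric(nrow(Xs)))
  if (nrow(Xs) == 1) preds <- matrix(preds, nrow = 1)
  rowMeans(preds) * object$y_scale + object$y_center
}

#' @export
print.ann_ensemble <- function(x, ...) {
  cat(sprintf("<ann_ensemble> %d nets, %d hidden units, features: %s\n",
              x$ensemble_size, x$hidden_units, paste(x$features, collapse = ", ")))
  invisible(x)
}

## ---- model bundles ---------------------------------------------------------

#' Fit a direct or class-conditional EE model bundle
#'
#' The central fitting entry point. `architecture = "direct"` fits a single
#' regressor on its preset feature list; `"class_conditional"` fits one
#' regressor per activity class, each trained only on windows of its true
#' class, to be routed at prediction time by true labels or by a fitted
#' activity-class gate.
#'
#' @param features a feature table from [assemble_feature_table()] with
#'   `ee_meas` labels and (for the class-conditional architecture)
#'   `activity_class` labels; `REE` must be present.
#' @param architecture `"class_conditional"` (default) or `"direct"`.
#' @param regressor `"mlr"` (default) or `"ann"`.
#' @param feature_sets named list of feature sets: for `"direct"` an element
#'   `direct`; for `"class_conditional"` one element per class. Defaults to
#'   the shipped presets.
#' @param classifier an optional fitted [knn_gate()] stored for
#'   classifier-routed prediction.
#' @param ... passed to the regressor fitter (e.g. `ensemble_size`, `seed`
#'   for `"ann"`).
#' @return an object of class `ee_bundle`.
#' @export
fit_ee_bundle <- function(features, architecture = c("class_conditional", "direct"),
                          regressor = c("mlr", "ann"), feature_sets = NULL,
                          classifier = NULL, ...) {
  architecture <- match.arg(architecture)
  regressor <- match.arg(regressor)
  y <- features$ee_meas
  if (anyNA(y)) stop_iscee("windows without measured EE in training table",
                           "iscee_data_error")
  fitter <- function(rows, fset, hidden) {
    if (regressor == "mlr") {
      relmlr(rows, rows$ee_meas, features = fset)
    } else {
      ann_ensemble(rows, rows$ee_meas, features = fset,
                   hidden_units = hidden %||% 3, ...)
    }
  }
  if (architecture == "direct") {
    preset <- feature_preset(paste0(regressor, "_direct"))
    fset <- (feature_sets$direct %||% preset$features)
    models <- list(direct = fitter(features, fset, preset$hidden_units))
  } else {
    if (!is.null(feature_sets) &&
        !all(ACTIVITY_CLASSES %in% names(feature_sets))) {
      stop_iscee("class_conditional needs one feature set per activity class",
                 "iscee_config_error")
    }
    models <- lapply(setNames(ACTIVITY_CLASSES, ACTIVITY_CLASSES), function(cl) {
      preset <- feature_preset(paste0(regressor, "_", cl))
      fset <- (feature_sets[[cl]] %||% preset$features)
      rows <- features[features$activity_class == cl, , drop = FALSE]
      if (nrow(rows) < length(fset) + 1) {
        stop_iscee(sprintf("class '%s' has %d windows for %d features",
                           cl, nrow(rows), length(fset)), "iscee_data_error")
      }
      fitter(rows, fset, preset$hidden_units)
    })
  }
  structure(list(architecture = architecture, regressor = regressor,
                 models = models, classifier = classifier),
            class = "ee_bundle")
}

#' @export
print.ee_bundle <- function(x, ...) {
  cat(sprintf("<ee_bundle> %s %s\n", toupper(x$regressor), x$architecture))
  for (nm in names(x$models)) {
    cat(sprintf("  %s: %s\n", nm, paste(x$models[[nm]]$features, collapse = ", ")))
  }
  invisible(x)
}

#' Predict per-window EE from a model bundle
#'
#' Class-conditional bundles route each window to its class model using
#' either the table's true labels (`class_source = "true_label"`) or the
#' bundle's stored activity-class gate (`"classifier"`). No silent
#' correction is applied: a misrouted window is scored by the wrong class
#' model.
#'
#' @param object a fitted [fit_ee_bundle()].
#' @param newdata a feature table.
#' @param class_source `"true_label"` (default) or `"classifier"`.
#' @param ... unused.
#' @return numeric vector of EE estimates (kcal/day), with the routing labels
#'   in attribute `"routed_class"` for class-conditional bundles.
#' @export
predict.ee_bundle <- function(object, newdata,
                              class_source = c("true_label", "classifier"), ...) {
  class_source <- match.arg(class_source)
  if (object$architecture == "direct") {
    return(predict(object$models$direct, newdata))
  }
  cls <- if (class_source == "true_label") {
    newdata$activity_class
  } else {
    if (is.null(object$classifier)) {
      stop_iscee("bundle has no stored classifier", "iscee_config_error")
    }
    as.character(predict(object$classifier, newdata))
  }
  if (is.null(cls)) stop_iscee("no class labels available for routing",
                               "iscee_data_error")
  pred <- rep(NA_real_, nrow(newdata))
  for (cl in unique(cls)) {
    sel <- cls == cl
    pred[sel] <- predict(object$models[[cl]], newdata[sel, , drop = FALSE])
  }
  attr(pred, "routed_class") <- cls
  pred
}

#' Leave-one-subject-out EE estimation errors
#'
#' Reuses the LOSO harness of the class gate for the regression stage: for
#' each subject, a bundle (and, when requested, the activity-class gate) is
#' fitted on all other subjects and applied to the held-out subject's
#' windows, so a subject's model never sees its own data.
#'
#' @param features feature table with `subject_id`, `activity_class`,
#'   `ee_meas` and all model features.
#' @param architecture,regressor,feature_sets,... passed to [fit_ee_bundle()].
#' @param class_source routing used at prediction time (ignored for
#'   `"direct"`).
#' @param k neighbours of the per-fold gate (default 10).
#' @return data frame with one row per window: labels, measured and
#'   predicted EE.
#' @export
loso_ee <- function(features, architecture = "class_conditional",
                    regressor = "mlr", class_source = "true_label",
                    feature_sets = NULL, k = 10, ...) {
  pred <- rep(NA_real_, nrow(features))
  for (s in unique(features$subject_id)) {
    test <- features$subject_id == s
    train <- features[!test, , drop = FALSE]
    gate <- if (architecture == "class_conditional" && class_source == "classifier") {
      knn_gate(train, train$activity_class, k = k)
    }
    bundle <- fit_ee_bundle(train, architecture = architecture,
                            regressor = regressor, feature_sets = feature_sets,
                            classifier = gate, ...)
    p <- if (architecture == "direct") {
      predict(bundle, features[test, , drop = FALSE])
    } else {
      predict(bundle, features[test, , drop = FALSE], class_source = class_source)
    }
    pred[test] <- as.numeric(p)
  }
  out <- features[, META_COLUMNS]
  out$ee_pred <- pred
  out
}
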