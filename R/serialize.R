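# JSON persistence for fitted models (classifier, regressors, bundles).

model_type <- function(object) {
  for (cl in c("relmlr", "ann_ensemble", "knn_gate", "ee_bundle")) {
    if (inherits(object, cl)) return(cl)
  }
  stop_iscee("object is not a serialisable iscee model", "iscee_config_error")
}

model_to_list <- function(object) {
  type <- model_type(object)
  x <- unclass(object)
  if (type == "knn_gate") x$train <- as.data.frame(x$train)
  if (type == "ee_bundle") {
    x$models <- lapply(x$models, model_to_list)
    x$classifier <- if (!is.null(x$classifier)) model_to_list(x$classifier)
  }
  c(list(.type = type), x)
}

list_to_model <- function(x) {
  type <- x$.type
  x$.type <- NULL
  if (type == "knn_gate") {
    x$train <- as.matrix(x$train)
    colnames(x$train) <- x$features
    x$center <- setNames(as.numeric(x$center), x$features)
    x$scale <- setNames(as.numeric(x$scale), x$features)
  }
  if (type == "relmlr") {
    x$coefficients <- setNames(as.numeric(x$coefficients),
                               c("(Intercept)", x$features))
  }
  if (type == "ann_ensemble") x$nets <- lapply(x$nets, as.numeric)
  if (type == "ee_bundle") {
    x$models <- lapply(x$models, list_to_model)
    x$classifier <- if (!is.null(x$classifier)) list_to_model(x$classifier)
  }
  structure(x, class = type)
}

#' Save or load a fitted model as a JSON document
#'
#' Works for [knn_gate()], [relmlr()], [ann_ensemble()] and
#' [fit_ee_bundle()] objects; numbers are written at full precision so
#' predictions round-trip exactly.
#'
#' @param object a fitted model.
#' @param path file path of the JSON document.
#' @return `read_model()` returns the restored model; `write_model()` the
#'   path, invisibly.
#' @export
write_model <- function(object, path) {
  jsonlite::write_json(model_to_list(object), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  list_to_model(jsonlite::read_json(path, simplifyVector = TRUE))
}
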