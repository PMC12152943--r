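#' Base learner specification
#'
#' Algorithm family, hyperparameters and seed for one probabilistic
#' classifier. Unspecified hyperparameters fall back to the package
#' defaults: random forest uses ranger with 500 trees and impurity
#' importance; gradient boosting uses xgboost with 50 rounds, depth 5 and
#' learning rate 0.1.
#'
#' @param algorithm `"random_forest"` or `"gradient_boosting"`.
#' @param hyperparameters named list overriding defaults (`num.trees`,
#'   `mtry`, `min.node.size` for RF; `nrounds`, `max_depth`,
#'   `learning_rate` for GB).
#' @param seed integer seed recorded in the spec and used for training.
#' @export
learner_spec <- function(algorithm = c("random_forest", "gradient_boosting"),
                         hyperparameters = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  structure(list(algorithm = algorithm,
                 hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "learner_spec")
}

# Train one probabilistic classifier. Internal: the consensus layer is the
# public surface.
fit_base_learner <- function(x, y, spec) {
  stopifnot(inherits(spec, "learner_spec"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (length(unique(y)) < 2L)
    stop_schema("training data contains a single class")
  hp <- spec$hyperparameters
  yf <- factor(y, levels = c("0", "1"))
  fit <- switch(spec$algorithm,
    random_forest = ranger::ranger(
      x = x, y = yf, probability = TRUE, importance = "impurity",
      num.trees = hp$num.trees %||% 500L,
      mtry = hp$mtry,
      min.node.size = hp$min.node.size %||% 10L,
      seed = spec$seed, num.threads = 1L),
    gradient_boosting = xgboost::xgb.train(
      params = xgboost::xgb.params(
        objective = "binary:logistic",
        max_depth = hp$max_depth %||% 5L,
        learning_rate = hp$learning_rate %||% 0.1,
        nthread = 1L, seed = spec$seed),
      data = xgboost::xgb.DMatrix(x, label = as.integer(y == 1),
                                  nthread = 1L),
      nrounds = hp$nrounds %||% 50L, verbose = 0L))
  structure(list(fit = fit, spec = spec, feature_ids = colnames(x)),
            class = "base_learner")
}

# Positive-class probability on aligned feature columns.
predict_prob <- function(model, newx) {
  newx <- check_features(newx, model$feature_ids)
  if (model$spec$algorithm == "random_forest") {
    pr <- stats::predict(model$fit, data = newx, num.threads = 1L)$predictions
    unname(pr[, "1"])
  } else {
    unname(stats::predict(model$fit, newx))
  }
}

# Per-feature importance aligned to the training feature ids (features a
# model never split on get 0).
learner_importance <- function(model) {
  imp <- stats::setNames(numeric(length(model$feature_ids)), model$feature_ids)
  if (model$spec$algorithm == "random_forest") {
    v <- ranger::importance(model$fit)
    imp[names(v)] <- v
  } else {
    tab <- xgboost::xgb.importance(model = model$fit)
    imp[tab$Feature] <- tab$Gain
  }
  imp
}

# Validate that newdata carries exactly the training features; reorder to
# the training order. Errors list the missing/extra columns.
check_features <- function(newx, feature_ids) {
  if (inherits(newx, "labeled_dataset")) newx <- newx$x
  newx <- as.matrix(newx)
  storage.mode(newx) <- "double"
  missing <- setdiff(feature_ids, colnames(newx))
  extra <- setdiff(colnames(newx), feature_ids)
  if (length(missing) || length(extra))
    stop_schema("feature space mismatch; missing: [",
                paste(utils::head(missing, 10), collapse = ", "),
                "], extra: [",
                paste(utils::head(extra, 10), collapse = ", "), "]")
  newx[, feature_ids, drop = FALSE]
}
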