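#' Confusion counts
#'
#' Tallies the 2x2 confusion table; the positive class is
#' cholestasis-positive (label 1 / "active").
#'
#' @param y_true binary truth vector (0/1).
#' @param y_pred binary predictions (0/1), or a [prediction_set()] whose
#'   labels are used.
#' @return object of class `confusion_counts` with fields TP, FP, TN, FN.
#' @export
confusion <- function(y_true, y_pred) {
  if (inherits(y_pred, "prediction_set"))
    y_pred <- as.integer(y_pred$label == "active")
  if (length(y_true) != length(y_pred))
    stop_schema("y_true and y_pred lengths differ")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop_schema("labels must be 0/1")
  confusion_counts(TP = sum(y_true == 1 & y_pred == 1),
                   FP = sum(y_true == 0 & y_pred == 1),
                   TN = sum(y_true == 0 & y_pred == 0),
                   FN = sum(y_true == 1 & y_pred == 0))
}

#' @rdname confusion
#' @param TP,FP,TN,FN non-negative integer counts.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0)) stop_schema("confusion counts must be non-negative")
  structure(as.list(as.numeric(counts)), names = names(counts),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy, Matthews correlation coefficient, sensitivity,
#' specificity, precision and balanced accuracy:
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' \deqn{balanced\ accuracy = (sensitivity + specificity)/2}
#' Any metric with a zero denominator is reported as `NA` (an explicit
#' undefined marker), never silently as 0.
#'
#' @param c a [confusion_counts()] object with a positive total.
#' @return list of class `metrics_report`.
#' @export
compute_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$TP + c$FP + c$TN + c$FN
  if (total == 0) stop_schema("all confusion counts are zero")
  sens <- safe_div(c$TP, c$TP + c$FN)
  spec <- safe_div(c$TN, c$TN + c$FP)
  mcc_den <- (c$TP + c$FP) * (c$TP + c$FN) * (c$TN + c$FP) * (c$TN + c$FN)
  mcc <- if (mcc_den == 0) NA_real_ else
    (c$TP * c$TN - c$FP * c$FN) / sqrt(mcc_den)
  structure(list(accuracy = (c$TP + c$TN) / total,
                 mcc = mcc,
                 sensitivity = sens,
                 specificity = spec,
                 precision = safe_div(c$TP, c$TP + c$FP),
                 balanced_accuracy = if (is.na(sens) || is.na(spec))
                   NA_real_ else (sens + spec) / 2,
                 counts = c),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  v <- unlist(x[c("accuracy", "mcc", "sensitivity", "specificity",
                  "precision", "balanced_accuracy")])
  print(round(v, digits))
  invisible(x)
}

band_labels <- function(boundaries) {
  c(sprintf("[0,%g)", boundaries[1]),
    sprintf("[%g,%g]", boundaries[1], boundaries[2]),
    sprintf("(%g,1]", boundaries[2]))
}

#' Tabulate compounds across probability bands per class
#'
#' Counts compounds of each cholestasis class falling in the low
#' `[0, low)`, middle `[low, high]` and high `(high, 1]` probability
#' bands; both boundaries belong to the middle (uncertain) band, matching
#' the semantics of [probability_range_filter()].
#'
#' @param mean_probabilities per-compound mean probabilities in \[0,1\].
#' @param y_true binary class labels (1 = cholestasis-positive).
#' @param boundaries band boundaries, default `c(0.35, 0.65)`.
#' @return object of class `band_table`: a 2 x 3 count matrix with rows
#'   `negative`, `positive`.
#' @export
band_table <- function(mean_probabilities, y_true, boundaries = c(0.35, 0.65)) {
  if (any(mean_probabilities < 0 | mean_probabilities > 1))
    stop_schema("probabilities must lie in [0, 1]")
  if (boundaries[1] >= boundaries[2]) stop_config("boundaries must increase")
  band <- ifelse(mean_probabilities < boundaries[1], 1L,
                 ifelse(mean_probabilities <= boundaries[2], 2L, 3L))
  counts <- rbind(negative = tabulate(band[y_true == 0], 3L),
                  positive = tabulate(band[y_true == 1], 3L))
  colnames(counts) <- band_labels(boundaries)
  structure(counts, class = c("band_table", "matrix", "array"),
            boundaries = boundaries)
}

#' Assemble a band table from printed per-class counts
#'
#' Convenience constructor for working directly with published band
#' counts.
#'
#' @param negative,positive length-3 count vectors (low, middle, high band).
#' @param boundaries band boundaries, default `c(0.35, 0.65)`.
#' @export
as_band_table <- function(negative, positive, boundaries = c(0.35, 0.65)) {
  stopifnot(length(negative) == 3L, length(positive) == 3L)
  counts <- rbind(negative = as.numeric(negative),
                  positive = as.numeric(positive))
  colnames(counts) <- band_labels(boundaries)
  structure(counts, class = c("band_table", "matrix", "array"),
            boundaries = boundaries)
}

#' @export
print.band_table <- function(x, ...) {
  cat("<band_table> compounds per probability band\n")
  print(unclass(x))
  invisible(x)
}

#' Metrics after excluding the uncertain band
#'
#' Drops the middle band and treats low-band compounds as predicted
#' inactive and high-band compounds as predicted active: TN = low-band
#' negatives, FN = low-band positives, FP = high-band negatives, TP =
#' high-band positives, then delegates to [compute_metrics()]. This is the
#' arithmetic that turns a probability-band table into the filtered
#' performance metrics.
#'
#' @param t a [band_table()] with exactly 3 bands.
#' @return a `metrics_report`.
#' @export
metrics_from_bands <- function(t) {
  stopifnot(inherits(t, "band_table"), ncol(t) == 3L)
  m <- unclass(t)
  if (sum(m[, c(1, 3)]) == 0)
    stop_schema("no compounds outside the uncertain band")
  compute_metrics(confusion_counts(TP = m["positive", 3], FP = m["negative", 3],
                                   TN = m["negative", 1], FN = m["positive", 1]))
}

#' Exclusion bookkeeping for the uncertain band
#'
#' @param t a [band_table()].
#' @return list with `count` (middle-band total), `neg`, `pos`
#'   (per-class middle-band counts) and `ratio` (negatives per positive,
#'   `NA` when no positives are excluded).
#' @export
excluded_summary <- function(t) {
  stopifnot(inherits(t, "band_table"), ncol(t) == 3L)
  m <- unclass(t)
  neg <- m["negative", 2]; pos <- m["positive", 2]
  list(count = neg + pos, neg = neg, pos = pos,
       ratio = safe_div(neg, pos))
}

#' Negative-to-positive class balance
#'
#' @param labels binary label vector (1 = positive).
#' @return negatives per positive as a real number; `NA` with a warning
#'   when there are no positives. Use [format_ratio()] for "R:1" display.
#' @export
class_balance <- function(labels) {
  pos <- sum(labels == 1)
  if (pos == 0) {
    warning("no positive compounds; class balance undefined")
    return(NA_real_)
  }
  sum(labels == 0) / pos
}

# stratified fold assignment: per-class shuffled round-robin keeps each
# class's fold sizes within one of each other
assign_folds <- function(y, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  names(fold) <- names(y)
  for (cl in unique(y)) {
    ids <- which(y == cl)
    fold[sample(ids)] <- rep_len(seq_len(k), length(ids))
  }
  fold
}

#' Pooled stratified k-fold cross-validation
#'
#' Splits the data into k stratified folds, applies the chosen
#' class-balancing procedure inside each training fold only, trains the
#' corresponding model (the 4-submodel undersampling consensus, a single
#' SMOTE-balanced learner, or an unbalanced learner) and predicts the
#' held-out fold. Out-of-fold predictions are pooled - every compound is
#' predicted exactly once - and the metrics and band table are computed on
#' the pooled predictions.
#'
#' @param d a [labeled_dataset()] with at least `k` members per class.
#' @param spec a [learner_spec()].
#' @param balancing `"undersample"` (default; trains a [fit_us_ensemble()]
#'   per fold), `"smote"`, or `"none"`.
#' @param k number of folds, default 10.
#' @param seed integer seed; fold assignment and per-fold training seeds
#'   derive from it.
#' @param n_subsets undersampling subsets, default 4.
#' @param k_neighbors SMOTE neighbours, default 5.
#' @param boundaries band boundaries for the pooled band table.
#' @return list of class `cv_result`: `pooled` (metrics_report on pooled
#'   predictions), `band` (band_table), `per_fold` (list of
#'   metrics_report), `predictions` (pooled [prediction_set()] plus truth).
#' @export
cross_validate <- function(d, spec, balancing = c("undersample", "smote", "none"),
                           k = 10L, seed, n_subsets = 4L, k_neighbors = 5L,
                           boundaries = c(0.35, 0.65)) {
  balancing <- match.arg(balancing)
  if (min(table(d$y)) < k)
    stop_config("each class needs at least k = ", k, " members")
  fold <- assign_folds(d$y, k, seed)
  fold_seeds <- derive_seeds(seed, k)
  preds <- vector("list", k)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    train <- subset_dataset(d, names(fold)[fold != f])
    test <- subset_dataset(d, names(fold)[fold == f])
    sp <- spec; sp$seed <- fold_seeds[f]
    ps <- switch(balancing,
      undersample = {
        subsets <- undersample_subsets(train, n_subsets, seed = fold_seeds[f])
        stats::predict(fit_us_ensemble(subsets, sp), test$x)
      },
      smote = {
        sm <- smote_oversample(train, k_neighbors, seed = fold_seeds[f])
        single_model_predictions(fit_base_learner(sm$x, sm$y, sp), test$x)
      },
      none = single_model_predictions(fit_base_learner(train$x, train$y, sp),
                                      test$x))
    per_fold[[f]] <- compute_metrics(confusion(test$y, ps))
    ps$y_true <- unname(test$y)
    preds[[f]] <- as.data.frame(ps)
  }
  pooled_df <- do.call(rbind, preds)
  pooled_df <- pooled_df[match(names(d$y), pooled_df$compound_id), ]
  pooled <- compute_metrics(confusion(pooled_df$y_true,
                                      as.integer(pooled_df$label == "active")))
  band <- band_table(pooled_df$mean_probability, pooled_df$y_true, boundaries)
  structure(list(pooled = pooled, band = band, per_fold = per_fold,
                 predictions = pooled_df, k = k, seed = as.integer(seed),
                 balancing = balancing),
            class = "cv_result")
}

single_model_predictions <- function(model, newx) {
  p <- predict_prob(model, newx)
  prediction_set(rownames(newx), p, as.integer(p >= 0.5),
                 ifelse(p >= 0.5, "active", "inactive"), n_members = 1L)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold pooled (%s balancing, seed %d)\n",
              x$k, x$balancing, x$seed))
  print(x$pooled)
  invisible(x)
}

#' Select the best model by balanced accuracy
#'
#' Balanced accuracies are compared after rounding to three decimals; ties
#' break by higher sensitivity, then higher MCC, then lexicographic name.
#' The choice is invariant to the order of the candidates.
#'
#' @param results named list of `metrics_report` objects (or `cv_result`s,
#'   whose pooled metrics are used).
#' @return the winning name.
#' @export
select_best <- function(results) {
  if (length(results) == 0L) stop_config("no candidate models")
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop_config("candidates must be named")
  get <- function(r, f) {
    if (inherits(r, "cv_result")) r <- r$pooled
    v <- r[[f]]
    if (is.na(v)) -Inf else v
  }
  ba <- round(vapply(results, get, numeric(1), "balanced_accuracy"), 3)
  sens <- vapply(results, get, numeric(1), "sensitivity")
  mcc <- vapply(results, get, numeric(1), "mcc")
  ord <- order(-ba, -sens, -mcc, names(results))
  names(results)[ord[1]]
}

#' Mean-scaled feature importance of an undersampling ensemble
#'
#' Each submodel's raw importance scores are scaled by that submodel's
#' maximum (the top feature maps to 1.0), the scaled scores are averaged
#' across the four submodels, and features are ranked in descending order
#' of the mean scaled influence. A submodel with all-zero importances
#' contributes zeros, with a warning.
#'
#' @param e a fitted [fit_us_ensemble()] object, or a list of named
#'   per-feature raw importance vectors (one per submodel, shared names).
#' @return data.frame of class `importance_ranking` with columns `rank`,
#'   `feature_id`, `mean_scaled_influence`.
#' @export
mean_scaled_importance <- function(e) {
  raw <- if (inherits(e, "us_ensemble")) {
    lapply(e$submodels, learner_importance)
  } else if (is.list(e) && all(vapply(e, is.numeric, logical(1)))) {
    e
  } else stop_config("expected a us_ensemble or a list of importance vectors")
  feats <- names(raw[[1]])
  scaled <- vapply(raw, function(v) {
    v <- v[feats]
    mx <- max(v)
    if (mx <= 0) {
      warning("submodel has all-zero feature importance; contributing zeros")
      return(v * 0)
    }
    v / mx
  }, numeric(length(feats)))
  infl <- rowMeans(scaled)
  ord <- order(-infl, names(infl))
  structure(data.frame(rank = seq_along(infl),
                       feature_id = names(infl)[ord],
                       mean_scaled_influence = unname(infl[ord]),
                       stringsAsFactors = FALSE),
            class = c("importance_ranking", "data.frame"))
}
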