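#' Per-compound consensus predictions
#'
#' @param compound_ids character ids.
#' @param mean_probability mean positive-class probability over members.
#' @param active_votes number of members voting active at the 0.5 cut.
#' @param label `"active"` or `"inactive"`.
#' @param excluded logical, set by [probability_range_filter()].
#' @param n_members ensemble size the votes are counted out of.
#' @return data.frame of class `prediction_set`.
#' @export
prediction_set <- function(compound_ids, mean_probability, active_votes,
                           label, excluded = FALSE, n_members = NA_integer_) {
  if (any(mean_probability < 0 | mean_probability > 1))
    stop_schema("mean_probability outside [0, 1]")
  if (!all(label %in% c("active", "inactive")))
    stop_schema("labels must be 'active' or 'inactive'")
  df <- data.frame(compound_id = as.character(compound_ids),
                   mean_probability = as.numeric(mean_probability),
                   active_votes = as.integer(active_votes),
                   label = as.character(label),
                   excluded = rep_len(as.logical(excluded), length(compound_ids)),
                   stringsAsFactors = FALSE)
  structure(df, class = c("prediction_set", "data.frame"),
            n_members = as.integer(n_members))
}

#' Fit the 4-submodel undersampling ensemble
#'
#' Trains one probabilistic classifier per undersampling subset (see
#' [undersample_subsets()]); exactly four subsets are required, each
#' containing both classes. Submodel seeds are derived deterministically
#' from `spec$seed`, so the same data and spec reproduce identical
#' predictions.
#'
#' @param subsets list of exactly 4 [labeled_dataset()]s.
#' @param spec a [learner_spec()].
#' @return object of class `us_ensemble`.
#' @seealso [predict.us_ensemble()], [mean_scaled_importance()]
#' @export
fit_us_ensemble <- function(subsets, spec) {
  if (length(subsets) != 4L)
    stop_config("the undersampling ensemble requires exactly 4 subsets, got ",
                length(subsets))
  seeds <- derive_seeds(spec$seed, 4L)
  submodels <- lapply(seq_along(subsets), function(i) {
    s <- subsets[[i]]
    sp <- spec; sp$seed <- seeds[i]
    fit_base_learner(s$x, s$y, sp)
  })
  feats <- lapply(submodels, function(m) m$feature_ids)
  if (!all(vapply(feats, identical, logical(1), feats[[1]])))
    stop_schema("subsets do not share one feature space")
  structure(list(submodels = submodels, spec = spec,
                 subset_manifest = lapply(subsets, function(s) rownames(s$x)),
                 feature_ids = feats[[1]]),
            class = "us_ensemble")
}

#' @export
print.us_ensemble <- function(x, ...) {
  cat(sprintf("<us_ensemble> 4 x %s submodels on %d features (seed %d)\n",
              x$spec$algorithm, length(x$feature_ids), x$spec$seed))
  invisible(x)
}

#' Consensus decision rules
#'
#' `us_consensus_label()` is the 4-submodel undersampling rule: three or
#' four active votes classify a compound active, none or one inactive, and
#' the two-vote tie is resolved by the mean probability at the 0.5 cut
#' (mean of 0.5 exactly is active). `expanded_consensus_label()` is the
#' 9-model majority rule: active iff at least `min_votes` members vote
#' active.
#'
#' @param active_votes integer vector of active votes per compound.
#' @param mean_probability mean member probability per compound.
#' @param min_votes majority threshold for the expanded rule, default 5.
#' @return character vector of `"active"`/`"inactive"`.
#' @export
us_consensus_label <- function(active_votes, mean_probability) {
  ifelse(active_votes >= 3, "active",
         ifelse(active_votes <= 1, "inactive",
                ifelse(mean_probability >= 0.5, "active", "inactive")))
}

#' @rdname us_consensus_label
#' @export
expanded_consensus_label <- function(active_votes, min_votes = 5L) {
  ifelse(active_votes >= min_votes, "active", "inactive")
}

#' Predict with the undersampling consensus vote rule
#'
#' Each submodel casts an active vote when its probability reaches 0.5.
#' Three or four votes classify the compound active; none or one,
#' inactive; at exactly two votes the tie is resolved by the mean of the
#' four probabilities (mean >= 0.5 is active). The mean probability is
#' always stored, because it also drives probability-range filtering.
#'
#' @param object a fitted [fit_us_ensemble()] ensemble.
#' @param newdata matrix/[binary_matrix] with the training feature columns.
#' @param ... unused.
#' @return a [prediction_set()].
#' @export
predict.us_ensemble <- function(object, newdata, ...) {
  newx <- check_features(newdata, object$feature_ids)
  probs <- vapply(object$submodels, predict_prob,
                  numeric(nrow(newx)), newx = newx)
  probs <- matrix(probs, nrow = nrow(newx))
  votes <- rowSums(probs >= 0.5)
  mean_p <- rowMeans(probs)
  prediction_set(rownames(newx), mean_p, votes,
                 us_consensus_label(votes, mean_p), n_members = 4L)
}

#' Fit the 9-model expanded consensus
#'
#' Combines the two undersampling ensembles (4 gradient-boosting and 4
#' random-forest submodels, sharing one majority-class partition by
#' default) with the better of the two SMOTE-trained single models,
#' selected by pooled cross-validated balanced accuracy (see
#' [select_best()]).
#'
#' @param train a [labeled_dataset()] containing both classes.
#' @param gb_spec,rf_spec [learner_spec()]s for the two undersampling
#'   ensembles.
#' @param seed integer master seed; partition, SMOTE and selection-CV seeds
#'   are derived from it.
#' @param n_subsets majority-class subsets, default 4.
#' @param k_neighbors SMOTE neighbours, default 5.
#' @param smote_select `"cv"` (default: pick GB vs RF by cross-validated
#'   balanced accuracy), or force `"gb"`/`"rf"`.
#' @param cv_k folds for the SMOTE-member selection, default 10.
#' @param shared_partition reuse one majority partition for both ensembles
#'   (default) or draw a fresh one for RF.
#' @return object of class `expanded_consensus` with 9 members.
#' @export
fit_expanded_consensus <- function(train, gb_spec, rf_spec, seed,
                                   n_subsets = 4L, k_neighbors = 5L,
                                   smote_select = c("cv", "gb", "rf"),
                                   cv_k = 10L, shared_partition = TRUE) {
  smote_select <- match.arg(smote_select)
  seeds <- derive_seeds(seed, 5L)
  subsets_gb <- undersample_subsets(train, n_subsets, seed = seeds[1])
  subsets_rf <- if (shared_partition) subsets_gb else
    undersample_subsets(train, n_subsets, seed = seeds[2])
  us_gb <- fit_us_ensemble(subsets_gb, gb_spec)
  us_rf <- fit_us_ensemble(subsets_rf, rf_spec)
  sm <- smote_oversample(train, k_neighbors, seed = seeds[3])
  cand <- list(gb = gb_spec, rf = rf_spec)
  choice <- if (smote_select == "cv") {
    cvres <- lapply(cand, function(sp) {
      sp$seed <- seeds[4]
      cross_validate(train, sp, balancing = "smote", k = cv_k,
                     seed = seeds[5], k_neighbors = k_neighbors)$pooled
    })
    select_best(cvres)
  } else smote_select
  sm_spec <- cand[[choice]]
  sm_spec$seed <- seeds[4]
  smote_model <- fit_base_learner(sm$x, sm$y, sm_spec)
  members <- c(us_gb$submodels, us_rf$submodels, list(smote_model))
  structure(list(members = members,
                 member_names = c(paste0("US_GB_", 1:4), paste0("US_RF_", 1:4),
                                  paste0("SMOTE_", toupper(choice))),
                 us_gb = us_gb, us_rf = us_rf,
                 smote_algorithm = choice,
                 feature_ids = us_gb$feature_ids, seed = as.integer(seed)),
            class = "expanded_consensus")
}

#' @export
print.expanded_consensus <- function(x, ...) {
  cat(sprintf("<expanded_consensus> 9 members (4 US_GB + 4 US_RF + SMOTE %s) on %d features\n",
              toupper(x$smote_algorithm), length(x$feature_ids)))
  invisible(x)
}

#' Predict with the 9-model majority rule
#'
#' Every member votes at the 0.5 probability cut; a compound is active
#' when at least five of the nine members vote active. The stored mean
#' probability is the mean over all nine members.
#'
#' @param object a fitted [fit_expanded_consensus()] object.
#' @param newdata matrix/[binary_matrix] with the training feature columns.
#' @param ... unused.
#' @return a [prediction_set()].
#' @export
predict.expanded_consensus <- function(object, newdata, ...) {
  newx <- check_features(newdata, object$feature_ids)
  probs <- vapply(object$members, predict_prob,
                  numeric(nrow(newx)), newx = newx)
  probs <- matrix(probs, nrow = nrow(newx))
  votes <- rowSums(probs >= 0.5)
  prediction_set(rownames(newx), rowMeans(probs), votes,
                 expanded_consensus_label(votes), n_members = 9L)
}

#' Probability-range confidence filter
#'
#' Excludes compounds whose mean probability lies in the uncertain band
#' `[low, high]` (boundaries inclusive; defaults 0.35 and 0.65) and
#' re-derives the retained labels from the mean probability alone:
#' below `low` inactive, above `high` active.
#'
#' @param p a [prediction_set()] with populated mean probabilities.
#' @param low,high band boundaries, `low < high`.
#' @return list with elements `retained` and `excluded`, two disjoint
#'   [prediction_set()]s whose union is the input.
#' @export
probability_range_filter <- function(p, low = 0.35, high = 0.65) {
  if (low >= high) stop_config("filter bounds must satisfy low < high")
  stopifnot(inherits(p, "prediction_set"))
  in_band <- p$mean_probability >= low & p$mean_probability <= high
  nm <- attr(p, "n_members")
  retained <- p[!in_band, , drop = FALSE]
  retained$label <- ifelse(retained$mean_probability > high, "active", "inactive")
  retained$excluded <- FALSE
  excluded <- p[in_band, , drop = FALSE]
  excluded$excluded <- TRUE
  list(retained = structure(retained,
                            class = c("prediction_set", "data.frame"),
                            n_members = nm),
       excluded = structure(excluded,
                            class = c("prediction_set", "data.frame"),
                            n_members = nm))
}

#' Write a prediction set to CSV
#' @param p a [prediction_set()].
#' @param path output CSV.
#' @export
write_prediction_set <- function(p, path) {
  utils::write.csv(as.data.frame(p), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
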