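#' Labeled modelling dataset
#'
#' Pairs a feature matrix with binary cholestasis labels (1 =
#' cholestasis-positive). Feature values are 0/1 for assembled fingerprints
#' but may be fractional after SMOTE interpolation.
#'
#' @param x numeric matrix with unique rownames (compound ids).
#' @param y binary labels, one per row of `x`.
#' @param provenance free-text tag recording how the dataset was produced.
#' @export
labeled_dataset <- function(x, y, provenance = "") {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop_schema("labeled_dataset needs unique rownames")
  if (length(y) != nrow(x)) stop_schema("labels length != rows")
  if (!all(y %in% c(0, 1))) stop_schema("labels must be 0/1")
  y <- as.integer(y)
  names(y) <- rownames(x)
  storage.mode(x) <- "double"
  structure(list(x = x, y = y, provenance = provenance),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d compounds x %d features; %d positive / %d negative (%s)\n",
              nrow(x$x), ncol(x$x), sum(x$y == 1L), sum(x$y == 0L),
              format_ratio(class_balance(x$y))))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

# restrict a labeled dataset to a set of compound ids, keeping original order
subset_dataset <- function(d, ids, provenance = d$provenance) {
  keep <- rownames(d$x)[rownames(d$x) %in% ids]
  labeled_dataset(d$x[keep, , drop = FALSE], d$y[keep], provenance)
}

#' Stratified train/test split
#'
#' The total training size is `floor(train_fraction * N)`; per-class
#' training counts follow largest-remainder apportionment of the class
#' quotas (`train_fraction * class size`), which keeps every class within
#' one compound of its exact quota. Membership within a class is random
#' under `seed`. Remainder ties go to the larger class, then to the
#' negative class.
#'
#' @param d a [labeled_dataset()] containing both classes.
#' @param train_fraction fraction of compounds for training, default 0.8.
#' @param seed integer seed controlling class-internal assignment.
#' @return list of class `split_result` with elements `train`, `test`,
#'   `seed`.
#' @export
stratified_split <- function(d, train_fraction = 0.8, seed) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_config("train_fraction must be in (0, 1)")
  classes <- c(0L, 1L)
  n_class <- c(sum(d$y == 0L), sum(d$y == 1L))
  if (any(n_class == 0L)) stop_schema("both classes must be present to split")
  n_total <- floor(train_fraction * length(d$y))
  quota <- train_fraction * n_class
  base <- floor(quota)
  rem <- n_total - sum(base)
  if (rem > 0) {
    # largest fractional remainder; ties to larger class, then class 0 first
    ord <- order(-(quota - base), -n_class, classes)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  set.seed(as.integer(seed))
  train_ids <- unlist(lapply(seq_along(classes), function(i) {
    ids <- names(d$y)[d$y == classes[i]]
    sample(ids, base[i])
  }))
  test_ids <- setdiff(names(d$y), train_ids)
  structure(list(train = subset_dataset(d, train_ids,
                                        paste0(d$provenance, " [train]")),
                 test = subset_dataset(d, test_ids,
                                       paste0(d$provenance, " [test]")),
                 seed = as.integer(seed)),
            class = "split_result")
}

#' Write a split manifest
#'
#' Two-column CSV `compound_id,partition` recording the split for
#' reproducibility.
#' @param s a `split_result`.
#' @param path output CSV path.
#' @export
write_split_manifest <- function(s, path) {
  df <- rbind(data.frame(compound_id = rownames(s$train$x), partition = "train"),
              data.frame(compound_id = rownames(s$test$x), partition = "test"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' SMOTE minority oversampling
#'
#' Grows the minority class to the size of the majority class by
#' interpolating between existing minority samples and their k nearest
#' minority neighbours (Euclidean distance, default k = 5). Each synthetic
#' row lies on the segment between a minority row and one of its
#' neighbours, so values may be fractional; original rows are preserved
#' unchanged. An already balanced dataset is returned as-is.
#'
#' @param d a [labeled_dataset()].
#' @param k_neighbors number of nearest minority neighbours, default 5.
#' @param seed integer seed.
#' @return a [labeled_dataset()] with exactly balanced classes; synthetic
#'   rows are named `syn_0001`, `syn_0002`, ...
#' @export
smote_oversample <- function(d, k_neighbors = 5L, seed) {
  n_pos <- sum(d$y == 1L); n_neg <- sum(d$y == 0L)
  if (n_pos == n_neg) return(d)
  minority <- if (n_pos < n_neg) 1L else 0L
  m_ids <- names(d$y)[d$y == minority]
  m <- length(m_ids)
  if (m <= k_neighbors)
    stop_config("minority class (", m, ") must exceed k_neighbors (",
                k_neighbors, "); use a smaller k")
  n_new <- max(n_pos, n_neg) - m
  xm <- d$x[m_ids, , drop = FALSE]
  dm <- as.matrix(stats::dist(xm))
  diag(dm) <- Inf
  # k nearest minority neighbours of each minority row (ties by index order)
  nn <- t(apply(dm, 1, function(r) order(r)[seq_len(k_neighbors)]))
  set.seed(as.integer(seed))
  base <- sample.int(m, n_new, replace = TRUE)
  pick <- nn[cbind(base, sample.int(k_neighbors, n_new, replace = TRUE))]
  u <- stats::runif(n_new)
  synth <- xm[base, , drop = FALSE] + u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  rownames(synth) <- sprintf("syn_%04d", seq_len(n_new))
  labeled_dataset(rbind(d$x, synth), c(d$y, rep(minority, n_new)),
                  paste0(d$provenance, " [SMOTE k=", k_neighbors,
                         " seed=", seed, "]"))
}

#' Partition the majority class into undersampling subsets
#'
#' Splits the majority class uniformly at random into `n_subsets` disjoint
#' near-equal parts (sizes differ by at most one) and pairs each part with
#' the full minority class, yielding the training sets for the
#' undersampling consensus submodels. When majority/n_subsets is smaller
#' than the minority class the imbalance simply inverts; no correction is
#' applied.
#'
#' @param d a [labeled_dataset()].
#' @param n_subsets number of majority subsets, default 4.
#' @param seed integer seed for the random partition.
#' @return list of [labeled_dataset()]s; each carries its majority ids in
#'   attribute `majority_ids`.
#' @export
undersample_subsets <- function(d, n_subsets = 4L, seed) {
  if (n_subsets < 1L) stop_config("n_subsets must be >= 1")
  n_pos <- sum(d$y == 1L); n_neg <- sum(d$y == 0L)
  majority <- if (n_neg >= n_pos) 0L else 1L
  maj_ids <- names(d$y)[d$y == majority]
  min_ids <- names(d$y)[d$y != majority]
  if (length(maj_ids) < n_subsets)
    stop_config("majority class smaller than n_subsets")
  set.seed(as.integer(seed))
  perm <- sample(maj_ids)
  sizes <- rep(length(maj_ids) %/% n_subsets, n_subsets)
  extra <- length(maj_ids) %% n_subsets
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lapply(seq_len(n_subsets), function(i) {
    ids <- perm[starts[i]:ends[i]]
    out <- subset_dataset(d, c(ids, min_ids),
                          paste0(d$provenance, " [US subset ", i, "/",
                                 n_subsets, " seed=", seed, "]"))
    attr(out, "majority_ids") <- sort(ids)
    out
  })
}
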