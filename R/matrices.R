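#' Binarize compound-target bioactivity records
#'
#' Collapses possibly repeated measurements per (compound, target) pair by
#' taking the maximum pChEMBL value (the highest reported potency) and sets
#' the interaction bit when that maximum reaches the activity threshold.
#' The default threshold of 5 corresponds to activity at 10 uM or better;
#' the comparison is inclusive (pChEMBL = 5 is active). Pairs with no
#' record are 0.
#'
#' @param records data.frame of activity records as returned by
#'   [read_activity_records()] (columns `compound_id`, `target_id`,
#'   `pchembl`, `standard_type`).
#' @param threshold pChEMBL activity cutoff, default 5.
#' @return a [binary_matrix] with block `"target"`, one row per distinct
#'   compound and one column per distinct target (order of first appearance).
#' @examples
#' recs <- data.frame(compound_id = c("c1", "c1"), target_id = c("t1", "t1"),
#'                    pchembl = c(4.2, 5.7), standard_type = c("IC50", "Ki"))
#' binarize_activities(recs)  # max rule: bit(c1, t1) = 1
#' @export
binarize_activities <- function(records, threshold = 5.0) {
  if (!is.finite(threshold)) stop_config("threshold must be finite")
  records <- validate_activity_records(records)
  compounds <- unique(records$compound_id)
  targets <- unique(records$target_id)
  bits <- matrix(0L, length(compounds), length(targets),
                 dimnames = list(compounds, targets))
  key <- paste(records$compound_id, records$target_id, sep = "\r")
  mx <- tapply(records$pchembl, key, max)
  pair <- do.call(rbind, strsplit(names(mx), "\r", fixed = TRUE))
  active <- mx >= threshold
  bits[pair[active, , drop = FALSE]] <- 1L
  binary_matrix(bits, block = "target")
}

#' Restrict a target matrix to liver-expressed genes
#'
#' Keeps only the columns whose target id is in the filter's gene set;
#' row order is preserved and rows are retained even if they become
#' all-zero. An empty filter yields a zero-column matrix with a warning.
#'
#' @param m target [binary_matrix].
#' @param f an [expression_filter()].
#' @export
filter_targets_by_tissue <- function(m, f) {
  keep <- colnames(m)[colnames(m) %in% f$liver_genes]
  if (length(keep) == 0L)
    warning("tissue filter removed every target column")
  m[, keep]
}

#' Merge known and predicted compound-target interactions
#'
#' Implements the predicted-target enrichment variants: with
#' `min_tools = 1` every tool prediction is included (+all), with 2 or 3
#' only pairs predicted by at least that many distinct tools (+2-C, +3-C).
#' Known interactions are always retained regardless of tool support.
#' Matrices are outer-aligned first: the compound and feature axes of the
#' result are the unions of all inputs, missing entries counting as 0.
#'
#' @param known target [binary_matrix] of experimentally known interactions.
#' @param tool_predictions list of target [binary_matrix] objects, one per
#'   prediction tool.
#' @param min_tools minimum number of distinct tools that must agree for a
#'   predicted pair to be included (1, 2 or 3).
#' @export
merge_predicted_targets <- function(known, tool_predictions, min_tools = 1L) {
  if (length(tool_predictions) == 0L) stop_config("no tool predictions supplied")
  if (min_tools < 1L || min_tools > length(tool_predictions))
    stop_config("min_tools must be between 1 and the number of tools (",
                length(tool_predictions), ")")
  all_m <- c(list(known), tool_predictions)
  compounds <- unique(unlist(lapply(all_m, rownames)))
  features <- unique(unlist(lapply(all_m, colnames)))
  align <- function(m) {
    out <- matrix(0L, length(compounds), length(features),
                  dimnames = list(compounds, features))
    out[rownames(m), colnames(m)] <- as.matrix(m)
    out
  }
  k <- align(known)
  support <- Reduce(`+`, lapply(tool_predictions, align))
  bits <- (k == 1L) | (support >= min_tools)
  binary_matrix(bits * 1L, block = "target")
}

#' Expand a target matrix to a pathway fingerprint
#'
#' For each compound, collects its active targets plus the first-degree
#' interactors of those targets, maps that protein set to pathways, and
#' sets a bit for every mapped pathway that is liver-expressed. Pathway
#' columns are the (sorted) liver-expressed pathway ids.
#'
#' `include_direct` controls whether the direct targets' own pathway
#' assignments contribute (default) or only the interactors' do.
#'
#' @param m target [binary_matrix].
#' @param im interactome map: named list `target_id -> interactor ids`.
#' @param pm pathway membership: named list `protein_id -> pathway ids`.
#' @param f an [expression_filter()]; only `liver_pathways` is consulted.
#' @param include_direct include the direct targets' pathways, default TRUE.
#' @return a [binary_matrix] with block `"pathway"`.
#' @export
derive_pathway_matrix <- function(m, im, pm, f, include_direct = TRUE) {
  pathways <- sort(f$liver_pathways)
  bits <- matrix(0L, nrow(m), length(pathways),
                 dimnames = list(rownames(m), pathways))
  if (length(pathways) > 0L) {
    for (i in seq_len(nrow(m))) {
      targets <- colnames(m)[as.matrix(m)[i, ] == 1L]
      interactors <- unique(unlist(im[intersect(targets, names(im))]))
      prots <- if (include_direct) union(targets, interactors) else interactors
      hit <- unique(unlist(pm[intersect(prots, names(pm))]))
      bits[i, intersect(hit, pathways)] <- 1L
    }
  }
  binary_matrix(bits, block = "pathway")
}

#' Transporter inhibition consensus bits
#'
#' A compound is called an active inhibitor of a transporter when at least
#' `min_votes` of the per-algorithm binary predictions are 1 (default 3,
#' applied identically to 5-algorithm and 4-algorithm vote lists).
#'
#' @param v a [transporter_vote_table()].
#' @param min_votes votes needed for an active call, default 3.
#' @return a [binary_matrix] with block `"transporter"`, columns in the
#'   table's transporter order.
#' @export
transporter_consensus <- function(v, min_votes = 3L) {
  stopifnot(inherits(v, "transporter_vote_table"))
  transporters <- attr(v, "transporters")
  compounds <- unique(v$compound_id)
  n_votes <- table(factor(v$compound_id, compounds),
                   factor(v$transporter, transporters))
  if (any(n_votes == 0)) {
    miss <- which(n_votes == 0, arr.ind = TRUE)[1, ]
    stop_schema("no transporter votes for compound ", compounds[miss[1]],
                ", transporter ", transporters[miss[2]])
  }
  ones <- tapply(v$prediction,
                 list(factor(v$compound_id, compounds),
                      factor(v$transporter, transporters)), sum)
  binary_matrix((ones >= min_votes) * 1L, block = "transporter")
}

#' Concatenate fingerprint blocks into one combined matrix
#'
#' Compounds are inner-joined (only compounds present in every block
#' survive; the first block's order is kept) and feature ids are qualified
#' with their block label (`target:P02768`) so that an identifier reused
#' across blocks cannot collide.
#'
#' @param blocks non-empty list of [binary_matrix] objects.
#' @return a [binary_matrix] with block `"combined"`.
#' @export
concat_blocks <- function(blocks) {
  if (length(blocks) == 0L) stop_config("no blocks to concatenate")
  common <- Reduce(intersect, lapply(blocks, rownames))
  if (length(common) == 0L)
    stop_schema("no compound is present in every block")
  common <- rownames(blocks[[1]])[rownames(blocks[[1]]) %in% common]
  dropped <- length(unique(unlist(lapply(blocks, rownames)))) - length(common)
  if (dropped > 0)
    message(dropped, " compound(s) missing from at least one block were dropped")
  parts <- lapply(blocks, function(b) {
    x <- as.matrix(b)[common, , drop = FALSE]
    if (ncol(x) > 0)
      colnames(x) <- paste(matrix_block(b), colnames(x), sep = ":")
    x
  })
  binary_matrix(do.call(cbind, parts), block = "combined")
}

#' Compounds unique in all three fingerprint spaces
#'
#' Compounds whose fingerprint row is duplicated by another compound's row
#' in the target, pathway, or substructure space are discarded: a duplicate
#' in any one space disqualifies. The transporter block is deliberately not
#' consulted. Row identity is compared within each matrix separately, over
#' the compounds the three matrices share.
#'
#' @param target_m,pathway_m,substructure_m the three [binary_matrix]
#'   fingerprints over a shared compound universe.
#' @return character vector of retained compound ids, in `target_m` order.
#' @export
unique_across <- function(target_m, pathway_m, substructure_m) {
  mats <- list(target_m, pathway_m, substructure_m)
  common <- Reduce(intersect, lapply(mats, rownames))
  common <- rownames(target_m)[rownames(target_m) %in% common]
  dup_in <- function(m) {
    x <- as.matrix(m)[common, , drop = FALSE]
    duplicated(x) | duplicated(x, fromLast = TRUE)
  }
  any_dup <- Reduce(`|`, lapply(mats, dup_in))
  common[!any_dup]
}
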