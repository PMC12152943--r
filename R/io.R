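# Readers/writers for the plain-text interchange formats. Delimiter is
# inferred from the file extension (.tsv/.txt -> tab, otherwise comma).

delim_for <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Write a binary matrix to CSV/TSV
#'
#' First column `compound_id`, remaining columns one per feature. The
#' reader/writer pair round-trips losslessly.
#'
#' @param m a [binary_matrix].
#' @param path output file; `.tsv` extension selects tab delimiting.
#' @param sep optional delimiter override.
#' @export
write_binary_matrix <- function(m, path, sep = NULL) {
  sep <- delim_for(path, sep)
  df <- data.frame(compound_id = rownames(m), as.matrix(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a binary matrix from CSV/TSV
#'
#' @param path file whose first column is `compound_id` and remaining
#'   columns are 0/1 feature bits.
#' @param block block label to attach, see [binary_matrix()].
#' @param sep optional delimiter override.
#' @return a [binary_matrix].
#' @export
read_binary_matrix <- function(path, block = "target", sep = NULL) {
  sep <- delim_for(path, sep)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 1L || names(df)[1] != "compound_id")
    stop_schema("binary matrix file must start with a compound_id column: ", path)
  bits <- as.matrix(df[, -1, drop = FALSE])
  binary_matrix(bits, compound_ids = df$compound_id,
                feature_ids = colnames(bits), block = block)
}

STANDARD_TYPES <- c("IC50", "EC50", "Ki", "Kd", "AC50", "Potency")

#' Read bioactivity records
#'
#' Expects the header `compound_id,target_id,pchembl,standard_type`.
#' pChEMBL is the negative decadic logarithm of a molar potency value
#' (IC50, EC50, Ki, Kd, AC50 or Potency).
#'
#' @param path CSV/TSV file of activity records.
#' @param sep optional delimiter override.
#' @return data.frame of validated activity records.
#' @export
read_activity_records <- function(path, sep = NULL) {
  sep <- delim_for(path, sep)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  validate_activity_records(df)
}

validate_activity_records <- function(df) {
  need <- c("compound_id", "target_id", "pchembl", "standard_type")
  if (!all(need %in% names(df)))
    stop_schema("activity records need columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop_schema("no activity records")
  df$compound_id <- as.character(df$compound_id)
  df$target_id <- as.character(df$target_id)
  if (any(!nzchar(df$compound_id)) || any(!nzchar(df$target_id)))
    stop_schema("activity records contain empty ids")
  bad <- which(!is.finite(df$pchembl))
  if (length(bad))
    stop_schema("non-finite pChEMBL value in activity record row(s) ",
                paste(utils::head(bad, 5), collapse = ", "),
                " (compound ", df$compound_id[bad[1]], ", target ",
                df$target_id[bad[1]], ")")
  unknown <- setdiff(unique(df$standard_type), STANDARD_TYPES)
  if (length(unknown))
    stop_schema("unknown standard_type: ", paste(unknown, collapse = ", "))
  df
}

#' Read an interactome edge list
#'
#' Two-column tab-separated file `target_id<TAB>interactor_id` (no header).
#' @param path TSV edge list.
#' @return named list mapping each target id to its unique first-degree
#'   interactor ids.
#' @export
read_interactome <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("target_id", "interactor_id"))
  lapply(split(df$interactor_id, df$target_id), unique)
}

#' Read protein-to-pathway membership
#'
#' Two-column tab-separated file `protein_id<TAB>pathway_id` (no header).
#' @param path TSV membership table.
#' @return named list mapping each protein id to its pathway ids.
#' @export
read_pathway_membership <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("protein_id", "pathway_id"))
  lapply(split(df$pathway_id, df$protein_id), unique)
}

#' Read a one-id-per-line filter list
#' @param path text file, one identifier per line.
#' @return deduplicated character vector.
#' @export
read_id_list <- function(path) {
  ids <- trimws(readLines(path, warn = FALSE))
  unique(ids[nzchar(ids)])
}

#' Liver expression filter
#'
#' Holds the liver-expressed gene and pathway id sets used to restrict
#' target and pathway fingerprints to hepatically relevant features. Either
#' set may be empty (a degenerate filter passing nothing).
#'
#' @param liver_genes character vector of protein/gene ids.
#' @param liver_pathways character vector of pathway ids.
#' @export
expression_filter <- function(liver_genes = character(0),
                              liver_pathways = character(0)) {
  structure(list(liver_genes = unique(as.character(liver_genes)),
                 liver_pathways = unique(as.character(liver_pathways))),
            class = "expression_filter")
}

#' Per-algorithm transporter inhibition votes
#'
#' Long-format table `compound_id, transporter, algorithm, prediction` with
#' binary predictions; one row per (compound, transporter, algorithm).
#' Nominally five algorithms per transporter, four for OATP1B1.
#'
#' @param df data.frame with the four columns above.
#' @return the validated data.frame, classed `transporter_vote_table`, with
#'   a `transporters` attribute giving column order for the consensus matrix.
#' @export
transporter_vote_table <- function(df) {
  need <- c("compound_id", "transporter", "algorithm", "prediction")
  if (!all(need %in% names(df)))
    stop_schema("transporter votes need columns: ", paste(need, collapse = ", "))
  df$compound_id <- as.character(df$compound_id)
  df$transporter <- as.character(df$transporter)
  df$algorithm <- as.character(df$algorithm)
  if (!all(df$prediction %in% c(0, 1)))
    stop_schema("transporter predictions must be 0/1")
  df$prediction <- as.integer(df$prediction)
  structure(df, class = c("transporter_vote_table", "data.frame"),
            transporters = unique(df$transporter))
}

#' Read transporter votes from CSV
#' @param path long-format CSV `compound_id,transporter,algorithm,prediction`.
#' @export
read_transporter_votes <- function(path) {
  transporter_vote_table(utils::read.csv(path, stringsAsFactors = FALSE,
                                         comment.char = "#"))
}
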