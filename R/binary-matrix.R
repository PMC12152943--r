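BLOCK_LABELS <- c("target", "pathway", "substructure", "transporter", "combined")

#' Binary fingerprint matrix
#'
#' A compounds x features 0/1 matrix with a block label identifying which
#' fingerprint it carries (known/predicted targets, Reactome-style pathways,
#' substructure keys, transporter-inhibition consensus bits, or a combined
#' block). This is the common currency of the package: every fingerprint
#' assembly step consumes and produces `binary_matrix` objects.
#'
#' @param bits matrix (or object coercible to one) of 0/1 values.
#' @param compound_ids row identifiers; defaults to `rownames(bits)`.
#' @param feature_ids column identifiers; defaults to `colnames(bits)`.
#' @param block one of `"target"`, `"pathway"`, `"substructure"`,
#'   `"transporter"`, `"combined"`.
#' @return an integer matrix of class `binary_matrix` with a `block`
#'   attribute.
#' @examples
#' m <- binary_matrix(rbind(c1 = c(t1 = 1, t2 = 0), c2 = c(1, 1)), block = "target")
#' coverage(m)
#' @export
binary_matrix <- function(bits, compound_ids = rownames(bits),
                          feature_ids = colnames(bits),
                          block = c("target", "pathway", "substructure",
                                    "transporter", "combined")) {
  block <- match.arg(block)
  bits <- as.matrix(bits)
  if (nrow(bits) < 1L) stop_schema("binary_matrix needs at least one compound row")
  if (is.null(compound_ids)) stop_schema("compound ids are required")
  compound_ids <- as.character(compound_ids)
  feature_ids <- as.character(feature_ids %||% character(0))
  if (length(compound_ids) != nrow(bits))
    stop_schema("compound_ids length != number of rows")
  if (length(feature_ids) != ncol(bits))
    stop_schema("feature_ids length != number of columns")
  if (anyDuplicated(compound_ids)) stop_schema("duplicate compound ids")
  if (ncol(bits) > 0 && anyDuplicated(feature_ids)) stop_schema("duplicate feature ids")
  if (any(!nzchar(compound_ids)) || any(!nzchar(feature_ids)))
    stop_schema("empty id strings are not allowed")
  storage.mode(bits) <- "integer"
  if (ncol(bits) > 0 && !all(bits %in% c(0L, 1L)))
    stop_schema("binary_matrix values must all be 0 or 1")
  dimnames(bits) <- list(compound_ids, feature_ids)
  structure(bits, class = c("binary_matrix", "matrix", "array"), block = block)
}

#' @export
is_binary_matrix <- function(x) inherits(x, "binary_matrix")

#' Block label of a binary matrix
#' @param m a [binary_matrix].
#' @export
matrix_block <- function(m) attr(m, "block")

#' @export
`[.binary_matrix` <- function(x, i, j, drop = FALSE) {
  bl <- attr(x, "block")
  y <- unclass(x)[i, j, drop = FALSE]
  binary_matrix(y, block = bl)
}

#' @export
as.matrix.binary_matrix <- function(x, ...) {
  y <- unclass(x)
  attr(y, "block") <- NULL
  y
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat(sprintf("<binary_matrix [%s]> %d compounds x %d features, coverage %s\n",
              matrix_block(x), nrow(x), ncol(x),
              if (ncol(x) > 0) format_percent(sum(x) / (nrow(x) * ncol(x))) else "n/a"))
  invisible(x)
}

#' Fraction of set bits in a binary matrix
#'
#' Matrix coverage = actual interactions / total possible interactions,
#' where total possible = compounds x features. Returned as a fraction in
#' \[0,1\]; use [format_percent()] at the reporting layer.
#'
#' @param m a [binary_matrix] with at least one row and one column.
#' @return numeric scalar in \[0,1\].
#' @export
coverage <- function(m) {
  if (nrow(m) == 0L || ncol(m) == 0L)
    stop_schema("coverage is undefined for a matrix with zero rows or columns")
  sum(m) / (nrow(m) * ncol(m))
}
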