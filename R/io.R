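#' Write a numeric matrix as TSV
#'
#' Row identifiers go into a leading `id` column; column identifiers form the
#' header. `format = "long"` instead writes one row per matrix cell
#' (`row_id`, `col_id`, `value`).
#'
#' @param m Matrix with dimnames.
#' @param path Output file path.
#' @param format `"wide"` (default) or `"long"`.
#' @export
write_matrix_tsv <- function(m, path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "wide") {
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(row_id = rownames(m)[row(m)],
                     col_id = colnames(m)[col(m)],
                     value = as.vector(m), stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a numeric matrix written by [write_matrix_tsv()]
#' @param path TSV file with an `id` column and one column per identifier.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write an association table as TSV
#'
#' Binary matrix form via [write_matrix_tsv()]; `format = "pairs"` writes the
#' known associations as a two-column `lncrna`/`disease` list instead.
#'
#' @param assoc An [association_table()].
#' @param path Output file path.
#' @param format `"matrix"` (default) or `"pairs"`.
#' @export
write_association_tsv <- function(assoc, path, format = c("matrix", "pairs")) {
  format <- match.arg(format)
  stopifnot(inherits(assoc, "association_table"))
  if (format == "matrix") {
    write_matrix_tsv(assoc$matrix, path)
  } else {
    idx <- which(assoc$matrix == 1, arr.ind = TRUE)
    df <- data.frame(lncrna = assoc$lncrna_ids[idx[, 1L]],
                     disease = assoc$disease_ids[idx[, 2L]],
                     stringsAsFactors = FALSE)
    df <- df[order(df$lncrna, df$disease), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read an association matrix TSV
#' @param path File written by [write_association_tsv()] in matrix format.
#' @return An [association_table()].
#' @export
read_association_tsv <- function(path) {
  association_table(read_matrix_tsv(path))
}

#' Write a disease ontology as a descriptor table
#' @param ontology A [disease_ontology()].
#' @param path Output TSV path (readable by [parse_descriptor_table()]).
#' @export
write_descriptor_table <- function(ontology, path) {
  stopifnot(inherits(ontology, "disease_ontology"))
  df <- data.frame(
    term_id = ontology$term_id,
    name = unname(ontology$name),
    tree_numbers = vapply(ontology$tree_numbers, paste, character(1),
                          collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
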