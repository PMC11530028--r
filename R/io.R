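#' Write a numeric matrix as TSV
#'
#' Plain tab-separated values, units in rows; no row names, optional column
#' names taken from the matrix.
#'
#' @param x Numeric matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  utils::write.table(as.matrix(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE,
                     col.names = !is.null(colnames(x)))
  invisible(path)
}

#' Read a numeric matrix from TSV
#'
#' @param path File written by [write_matrix_tsv()] (or any numeric TSV).
#' @param header Whether the first line holds column names.
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path, header = FALSE) {
  as.matrix(utils::read.table(path, sep = "\t", header = header))
}
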