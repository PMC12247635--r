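#' Read an omics matrix from TSV
#'
#' Expected layout: header row of feature IDs, first column sample IDs,
#' tab-separated numeric body; empty fields or "NA" mark missing values.
#'
#' @param path TSV path.
#' @return numeric matrix, samples x features.
#' @export
read_omics_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("", "NA"))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Write an omics matrix to TSV
#'
#' Inverse of [read_omics_tsv()]; missing values written as "NA".
#'
#' @param m numeric matrix, samples x features, with dimnames.
#' @param path output path.
#' @export
write_omics_tsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# plain-TSV helpers used throughout the pipeline
read_tsv <- function(path)
  utils::read.delim(path, check.names = FALSE, na.strings = c("", "NA"))

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
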