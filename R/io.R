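# Plain TSV readers/writers for the pipeline's standard inputs and
# outputs. All matrices are gene x sample with a header row; the first
# column holds gene symbols.

#' Read a gene x sample expression matrix from TSV
#' @param path TSV path; first column gene symbols, remaining columns samples.
#' @return numeric matrix with dimnames.
#' @export
read_expression_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a gene x sample matrix as TSV
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param id_col name of the first (row-identifier) column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene") {
  d <- data.frame(rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  colnames(d)[1] <- id_col
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read sample metadata (sample_id, age, sex[, cohort]) from TSV
#' @param path TSV path.
#' @return data.frame.
#' @export
read_metadata_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "age", "sex")
  missing <- setdiff(need, colnames(d))
  if (length(missing) > 0)
    stop("metadata missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  d
}

#' Read a gene catalog (symbol, class) from TSV
#' @param path TSV path; class values such as RBP, TF, other.
#' @return data.frame.
#' @export
read_catalog_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("symbol", "class"), colnames(d))
  if (length(missing) > 0)
    stop("catalog missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  d
}

#' Read an ortholog map (human_symbol, rodent_symbol) from TSV
#' @param path TSV path.
#' @return data.frame.
#' @export
read_orthologs_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("human_symbol", "rodent_symbol"), colnames(d))
  if (length(missing) > 0)
    stop("ortholog map missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  d
}

#' Write a plain data.frame as TSV
#' @param d data.frame.
#' @param path output path.
#' @export
write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a network's edge list as a two-column TSV
#' @param net an \code{igraph} graph.
#' @param path output path.
#' @export
write_edges_tsv <- function(net, path) {
  el <- igraph::as_edgelist(net)
  d <- data.frame(symbol_a = el[, 1], symbol_b = el[, 2],
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
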