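#' Read and write the package's plain-text exchange formats
#'
#' Long bioactivity records, view matrices and cluster assignments travel as
#' TSV; pathway sets as GMT (via \pkg{fgsea}).
#'
#' @param records,path,view,assignment see individual functions.
#' @name panel_io
NULL

#' @rdname panel_io
#' @export
write_records_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname panel_io
#' @export
read_records_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname panel_io
#' @export
write_view_tsv <- function(view, path) {
  df <- data.frame(cell_line_id = rownames(view), view, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname panel_io
#' @export
read_view_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname panel_io
#' @export
write_clusters_tsv <- function(assignment, path) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  df <- data.frame(compound_id = names(assignment$compound_cluster),
                   cluster = as.integer(assignment$compound_cluster))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pathway sets from a GMT file
#'
#' Thin wrapper over `fgsea::gmtPathways()` returning a named list of feature
#' (gene) name vectors usable by [pathway_expression()].
#' @param path path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    stopf("reading GMT files requires the 'fgsea' package")
  }
  fgsea::gmtPathways(path)
}
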