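#' Encode cell lines as descriptor vectors
#'
#' Produces the cell line half of the pair descriptor, one row per cell line:
#' \describe{
#'   \item{`view`}{the profiling view matrix passed through unchanged.}
#'   \item{`dirac`}{cell line identity fingerprints: row i is the i-th
#'     standard basis vector, `CLIFP(i, j) = delta(i - j)`. No information is
#'     shared across cell lines.}
#'   \item{`multitask`}{`MLT(i, j) = (1 + delta(i - j)) / 2`: unit diagonal,
#'     1/2 elsewhere, placing all cell lines at equal distance while allowing
#'     sharing.}
#'   \item{`correlation`}{pairwise Spearman rank correlation of the cell
#'     lines' profile rows (e.g. transcript or protein levels).}
#' }
#' The `dirac` and `multitask` encodings cannot represent a cell line absent
#' from training, so they are refused by leave-one-cell-line/tissue-out
#' validation (see [run_strategy()]).
#'
#' @param cell_line_ids character vector fixing the row order of the encoding.
#' @param mode one of `"view"`, `"dirac"`, `"multitask"`, `"correlation"`.
#' @param source_view cell line x feature matrix (rownames covering
#'   `cell_line_ids`); required for `view` and `correlation` modes.
#' @return An object of class `cell_encoding`: numeric matrix with rownames
#'   `cell_line_ids` and attribute `mode`.
#' @export
encode_cell_lines <- function(cell_line_ids,
                              mode = c("view", "dirac", "multitask", "correlation"),
                              source_view = NULL) {
  mode <- match.arg(mode)
  ids <- as.character(cell_line_ids)
  n <- length(ids)
  if (n < 1) stopf("'cell_line_ids' must be non-empty")
  if (mode %in% c("view", "correlation")) {
    if (is.null(source_view)) stopf("mode '%s' requires 'source_view'", mode)
    missing <- setdiff(ids, rownames(source_view))
    if (length(missing)) stopf("source_view lacks cell line(s): %s",
                               paste(missing, collapse = ", "))
    v <- source_view[ids, , drop = FALSE]
  }
  m <- switch(mode,
    view = v,
    dirac = {
      d <- diag(n)
      dimnames(d) <- list(ids, ids)
      d
    },
    multitask = {
      d <- (diag(n) + 1) / 2
      dimnames(d) <- list(ids, ids)
      d
    },
    correlation = {
      const <- apply(v, 1, function(r) stats::sd(r) == 0 || !is.finite(stats::sd(r)))
      if (any(const)) stopf("constant profile row(s) make correlation undefined: %s",
                            paste(ids[const], collapse = ", "))
      r <- stats::cor(t(v), method = "spearman")
      dimnames(r) <- list(ids, ids)
      r
    }
  )
  structure(m, mode = mode, class = c("cell_encoding", "matrix", "array"))
}

encoding_mode <- function(enc) attr(enc, "mode")

#' @export
print.cell_encoding <- function(x, ...) {
  cat(sprintf("Cell line encoding (%s): %d cell lines x %d features\n",
              encoding_mode(x), nrow(x), ncol(x)))
  invisible(x)
}
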