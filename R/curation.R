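#' Aggregate replicate bioactivity records into a modelling-ready panel
#'
#' Collapses a long table of replicate pGI50 measurements to one row per
#' (compound, cell line) pair: the mean pGI50, the sample standard deviation
#' of the replicates as the experimental uncertainty (absent for single
#' measurements), and the replicate count. A default uncertainty in pGI50
#' units is recorded on the panel and substituted wherever the per-pair sd is
#' unavailable (e.g. by [performance_bounds()]); if not supplied it is set to
#' the mean of the available per-pair replicate sds.
#'
#' @param records data frame with columns `compound_id`, `cell_line_id`,
#'   `pGI50` (finite), and optionally `replicate_index`.
#' @param tissues named character vector mapping every cell line id to a
#'   tissue label.
#' @param default_uncertainty fallback experimental uncertainty, pGI50 units.
#'   `NULL` (default) means "mean of the available replicate sds".
#' @return An object of class `pgm_panel`: a list with `pairs` (data frame
#'   `compound_id, cell_line_id, y, sigma, n_replicates`), `tissues`, and
#'   `default_uncertainty`.
#' @export
aggregate_replicates <- function(records, tissues, default_uncertainty = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0) stopf("'records' must be a non-empty data frame")
  need <- c("compound_id", "cell_line_id", "pGI50")
  if (!all(need %in% names(records))) {
    stopf("'records' must have columns %s", paste(need, collapse = ", "))
  }
  bad <- which(!is.finite(records$pGI50))
  if (length(bad)) stopf("non-finite pGI50 at record index %d", bad[1])
  key <- paste(records$compound_id, records$cell_line_id, sep = "\r")
  y <- tapply(records$pGI50, key, mean)
  sds <- tapply(records$pGI50, key, function(v) if (length(v) >= 2) stats::sd(v) else NA_real_)
  nrep <- tapply(records$pGI50, key, length)
  parts <- strsplit(names(y), "\r", fixed = TRUE)
  pairs <- data.frame(
    compound_id = vapply(parts, `[`, "", 1L),
    cell_line_id = vapply(parts, `[`, "", 2L),
    y = as.numeric(y),
    sigma = as.numeric(sds),
    n_replicates = as.integer(nrep),
    stringsAsFactors = FALSE
  )
  rownames(pairs) <- NULL
  missing_cl <- setdiff(unique(pairs$cell_line_id), names(tissues))
  if (length(missing_cl)) {
    stopf("no tissue label for cell line(s): %s", paste(missing_cl, collapse = ", "))
  }
  if (is.null(default_uncertainty)) {
    default_uncertainty <- if (all(is.na(pairs$sigma))) NA_real_ else mean(pairs$sigma, na.rm = TRUE)
  }
  new_pgm_panel(pairs, tissues[sort(unique(pairs$cell_line_id))], default_uncertainty)
}

new_pgm_panel <- function(pairs, tissues, default_uncertainty) {
  structure(list(pairs = pairs, tissues = tissues,
                 default_uncertainty = default_uncertainty),
            class = "pgm_panel")
}

#' Build a `pgm_panel` directly from a synthetic panel
#'
#' Convenience wrapper: aggregates the replicate records of a
#' [generate_panel()] result with its tissue annotation.
#'
#' @param sp a `synthetic_panel`.
#' @param default_uncertainty see [aggregate_replicates()].
#' @return A `pgm_panel`.
#' @export
as_pgm_panel <- function(sp, default_uncertainty = NULL) {
  if (!inherits(sp, "synthetic_panel")) stopf("'sp' must be a synthetic_panel")
  aggregate_replicates(sp$records, sp$tissues, default_uncertainty)
}

#' @export
print.pgm_panel <- function(x, ...) {
  n_c <- length(unique(x$pairs$compound_id))
  n_l <- length(unique(x$pairs$cell_line_id))
  cat(sprintf("pGI50 panel: %d pairs (%d compounds x %d cell lines, completeness %.2f%%)\n",
              nrow(x$pairs), n_c, n_l, 100 * nrow(x$pairs) / (n_c * n_l)))
  cat(sprintf("  tissues: %d; default uncertainty: %s pGI50 units\n",
              length(unique(x$tissues)), format(x$default_uncertainty, digits = 3)))
  invisible(x)
}

#' @export
summary.pgm_panel <- function(object, ...) {
  p <- object$pairs
  out <- list(
    n_pairs = nrow(p),
    n_compounds = length(unique(p$compound_id)),
    n_cell_lines = length(unique(p$cell_line_id)),
    completeness = nrow(p) / (length(unique(p$compound_id)) * length(unique(p$cell_line_id))),
    y_range = range(p$y),
    multi_replicate_fraction = mean(p$n_replicates >= 2),
    default_uncertainty = object$default_uncertainty
  )
  class(out) <- "summary.pgm_panel"
  out
}

#' @export
print.summary.pgm_panel <- function(x, ...) {
  cat(sprintf("%d pairs, %d compounds, %d cell lines (completeness %.2f%%)\n",
              x$n_pairs, x$n_compounds, x$n_cell_lines, 100 * x$completeness))
  cat(sprintf("pGI50 range %.2f..%.2f; %.1f%% of pairs multi-replicate; default sigma %.3f\n",
              x$y_range[1], x$y_range[2], 100 * x$multi_replicate_fraction,
              x$default_uncertainty))
  invisible(x)
}

#' Filter a panel by bioactivity spread or replicate support
#'
#' Two curation rules:
#' \describe{
#'   \item{`spread`}{keeps every pair of those compounds whose cross-cell-line
#'     standard deviation of the mean pGI50 is strictly higher than `theta`
#'     (compounds with a dynamic range of bioactivities across the panel).}
#'   \item{`min_replicates`}{keeps the pairs whose replicate count is at least
#'     `k` (high-confidence measurements).}
#' }
#'
#' @param panel a `pgm_panel`.
#' @param rule `"spread"` or `"min_replicates"`.
#' @param theta spread threshold in pGI50 units (strict inequality).
#' @param k minimum replicate count.
#' @return The filtered `pgm_panel` (annotations preserved).
#' @export
filter_dataset <- function(panel, rule = c("spread", "min_replicates"),
                           theta = 0.5, k = 2L) {
  stopifnot(inherits(panel, "pgm_panel"))
  rule <- match.arg(rule)
  p <- panel$pairs
  if (rule == "spread") {
    if (!is.numeric(theta) || theta < 0) stopf("'theta' must be >= 0")
    spread <- tapply(p$y, p$compound_id, function(v) if (length(v) >= 2) stats::sd(v) else NA_real_)
    keep_cpd <- names(spread)[!is.na(spread) & spread > theta]
    keep <- p$compound_id %in% keep_cpd
  } else {
    if (!is.numeric(k) || k < 1) stopf("'k' must be >= 1")
    keep <- p$n_replicates >= k
  }
  new_pgm_panel(p[keep, , drop = FALSE], panel$tissues, panel$default_uncertainty)
}

#' Matrix completeness of a panel
#'
#' Fraction of the compound x cell line grid that carries a measurement.
#' @param panel a `pgm_panel`.
#' @return A fraction in (0, 1].
#' @export
completeness <- function(panel) {
  stopifnot(inherits(panel, "pgm_panel"))
  p <- panel$pairs
  nrow(p) / (length(unique(p$compound_id)) * length(unique(p$cell_line_id)))
}
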