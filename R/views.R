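#' View-assembly recipes
#'
#' Recipes transform a dense cell line x feature profiling matrix into a
#' modelling-ready "dataset view":
#' \describe{
#'   \item{`recipe_gene_subset(features)`}{select the named columns.}
#'   \item{`recipe_pathway_average(sets)`}{replace columns by per-set means
#'     (one column per named feature set, e.g. pathway-level expression).}
#'   \item{`recipe_ternary_cnv(high, low)`}{encode copy-number log-ratios as
#'     1 (gain, value > `high`), -1 (loss, value < `low`) and 0 otherwise;
#'     defaults 0.58 (>3N) and -1 (<1N).}
#'   \item{`recipe_top_variance(m)`}{keep the `m` features with highest
#'     cross-cell-line variance.}
#'   \item{`recipe_concatenate(views)`}{column-bind a list of views.}
#' }
#'
#' @param features character vector of column names.
#' @param sets named list of character vectors (feature sets).
#' @param high,low thresholds for the ternary coding.
#' @param m number of features to keep.
#' @param views list of matrices to concatenate (row sets must match).
#' @name view_recipes
NULL

#' @rdname view_recipes
#' @export
recipe_gene_subset <- function(features) {
  structure(list(type = "gene_subset", features = features), class = "view_recipe")
}

#' @rdname view_recipes
#' @export
recipe_pathway_average <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == "")) stopf("'sets' must be a named list")
  if (any(lengths(sets) == 0)) stopf("empty pathway in 'sets'")
  structure(list(type = "pathway_average", sets = sets), class = "view_recipe")
}

#' @rdname view_recipes
#' @export
recipe_ternary_cnv <- function(high = 0.58, low = -1) {
  if (low >= high) stopf("'low' must be below 'high'")
  structure(list(type = "ternary_cnv", high = high, low = low), class = "view_recipe")
}

#' @rdname view_recipes
#' @export
recipe_top_variance <- function(m) {
  m <- check_count(m, "m")
  structure(list(type = "top_variance", m = m), class = "view_recipe")
}

#' @rdname view_recipes
#' @export
recipe_concatenate <- function(views) {
  structure(list(type = "concatenate", views = views), class = "view_recipe")
}

#' Assemble a dataset view from a profiling matrix and a recipe
#'
#' Applies one of the [view_recipes] to a dense profiling matrix. Views must
#' be complete: missing values in the input fail assembly rather than being
#' silently imputed.
#'
#' @param profile numeric matrix, rows = cell lines (rownames required),
#'   columns = named features. Ignored (may be `NULL`) for
#'   `recipe_concatenate`.
#' @param recipe a `view_recipe`.
#' @return A numeric matrix with the same rows; attribute `provenance` records
#'   the recipe type.
#' @export
assemble_view <- function(profile, recipe) {
  if (!inherits(recipe, "view_recipe")) stopf("'recipe' must be a view_recipe")
  if (recipe$type != "concatenate") {
    if (!is.matrix(profile) || is.null(rownames(profile))) {
      stopf("'profile' must be a matrix with cell line rownames")
    }
    if (anyNA(profile)) stopf("profile contains missing values; views must be complete")
  }
  out <- switch(recipe$type,
    gene_subset = {
      missing <- setdiff(recipe$features, colnames(profile))
      if (length(missing)) stopf("features absent from profile: %s", paste(missing, collapse = ", "))
      profile[, recipe$features, drop = FALSE]
    },
    pathway_average = {
      all_genes <- unique(unlist(recipe$sets))
      missing <- setdiff(all_genes, colnames(profile))
      if (length(missing)) stopf("features absent from profile: %s", paste(missing, collapse = ", "))
      m <- vapply(recipe$sets, function(g)
        rowMeans(profile[, g, drop = FALSE]), numeric(nrow(profile)))
      m <- matrix(m, nrow = nrow(profile),
                  dimnames = list(rownames(profile), names(recipe$sets)))
      m
    },
    ternary_cnv = {
      m <- matrix(0, nrow(profile), ncol(profile), dimnames = dimnames(profile))
      m[profile > recipe$high] <- 1
      m[profile < recipe$low] <- -1
      m
    },
    top_variance = {
      v <- apply(profile, 2, stats::var)
      if (recipe$m > ncol(profile)) stopf("'m' exceeds the number of features")
      keep <- order(v, decreasing = TRUE)[seq_len(recipe$m)]
      profile[, sort(keep), drop = FALSE]
    },
    concatenate = {
      vs <- recipe$views
      if (length(vs) < 1) stopf("nothing to concatenate")
      rn <- rownames(vs[[1]])
      for (v in vs) {
        if (!identical(rownames(v), rn)) stopf("views to concatenate must share the same row set and order")
        if (anyNA(v)) stopf("view contains missing values; views must be complete")
      }
      do.call(cbind, vs)
    }
  )
  attr(out, "provenance") <- recipe$type
  out
}
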