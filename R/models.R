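#' Model configuration for pair-descriptor regressors
#'
#' Holds the learner choice and its parameters. The random forest defaults
#' are 100 trees, variance (mean-squared-error) split criterion, minimum node
#' size 1 (fully grown trees) and `mtry` equal to the input dimensionality
#' (`mtry = NULL`); `mtry = "sqrt"` selects `floor(sqrt(d))` descriptors per
#' split, the standard regression-forest compromise used by the panel-scale
#' validation and conformal stages, where full-`mtry` forests are
#' prohibitively slow. The radial-kernel SVM is tuned by an internal 10-fold
#' cross-validated grid search over `C` in \{2^-8, 2^-6, ..., 2^2, 10, 100,
#' 1000\} and the kernel width `sigma` in \{2^-8, 2^-6, ..., 2^2\}, minimizing
#' CV RMSE; ties break toward smaller `C`, then larger `sigma`. `sigma` is the
#' bandwidth of `k(u, v) = exp(-||u - v||^2 / (2 sigma^2))`, i.e.
#' `gamma = 1 / (2 sigma^2)` in \pkg{e1071}'s parameterization.
#'
#' @param learner `"rf"` or `"svm"`.
#' @param num_trees forest size.
#' @param mtry `NULL` (input dimensionality), `"sqrt"`, or an integer.
#' @param min_node_size minimal node size (1 = fully grown).
#' @param c_grid,sigma_grid SVM tuning grids.
#' @param tune_folds folds of the internal SVM grid-search CV.
#' @param scale standardize descriptor columns (training statistics) for the
#'   SVM; forests are never rescaled.
#' @param seed integer seed making fits reproducible.
#' @return An object of class `model_config`.
#' @export
model_config <- function(learner = c("rf", "svm"),
                         num_trees = 100L,
                         mtry = NULL,
                         min_node_size = 1L,
                         c_grid = c(2^seq(-8, 2, by = 2), 10, 100, 1000),
                         sigma_grid = 2^seq(-8, 2, by = 2),
                         tune_folds = 10L,
                         scale = TRUE,
                         seed = 1L) {
  learner <- match.arg(learner)
  num_trees <- check_count(num_trees, "num_trees")
  if (!is.null(mtry) && !identical(mtry, "sqrt")) mtry <- check_count(mtry, "mtry")
  min_node_size <- check_count(min_node_size, "min_node_size")
  if (length(c_grid) < 1 || length(sigma_grid) < 1) stopf("SVM grids must be non-empty")
  structure(list(learner = learner, num_trees = num_trees, mtry = mtry,
                 min_node_size = min_node_size, c_grid = c_grid,
                 sigma_grid = sigma_grid, tune_folds = tune_folds,
                 scale = scale, seed = as.integer(seed)),
            class = "model_config")
}

resolve_mtry <- function(config, d) {
  if (is.null(config$mtry)) d
  else if (identical(config$mtry, "sqrt")) max(1L, floor(sqrt(d)))
  else min(as.integer(config$mtry), d)
}

#' Build a pair-descriptor table
#'
#' One row per observed (compound, cell line) pair, with descriptor
#' `[compound fingerprint || cell line encoding]` and target `y` (mean pGI50).
#' With `enc = NULL` the descriptor is the fingerprint alone (compound-only /
#' QSAR-family mode).
#'
#' @param panel a `pgm_panel`.
#' @param fp fingerprint matrix with rownames covering the panel's compounds.
#' @param enc a [encode_cell_lines()] result covering the panel's cell lines,
#'   or `NULL`.
#' @return An object of class `pair_table`: list with `x` (descriptor
#'   matrix), `y`, and `pairs` (the panel rows used, in the same order).
#' @export
build_pair_table <- function(panel, fp, enc = NULL) {
  stopifnot(inherits(panel, "pgm_panel"))
  p <- panel$pairs
  miss_c <- setdiff(unique(p$compound_id), rownames(fp))
  if (length(miss_c)) stopf("fingerprints missing for compound(s): %s",
                            paste(utils::head(miss_c, 5), collapse = ", "))
  xc <- fp[p$compound_id, , drop = FALSE]
  if (!is.null(enc)) {
    miss_l <- setdiff(unique(p$cell_line_id), rownames(enc))
    if (length(miss_l)) stopf("encoding missing for cell line(s): %s",
                              paste(miss_l, collapse = ", "))
    xl <- enc[p$cell_line_id, , drop = FALSE]
    colnames(xl) <- paste0("cl_", seq_len(ncol(xl)))
    x <- cbind(xc, xl)
  } else {
    x <- xc
  }
  rownames(x) <- NULL
  storage.mode(x) <- "double"
  structure(list(x = x, y = p$y, pairs = p,
                 encoding_mode = if (is.null(enc)) NULL else encoding_mode(enc)),
            class = "pair_table")
}

subset_pair_table <- function(table, idx) {
  structure(list(x = table$x[idx, , drop = FALSE], y = table$y[idx],
                 pairs = table$pairs[idx, , drop = FALSE],
                 encoding_mode = table$encoding_mode),
            class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("Pair table: %d pairs x %d descriptors (%s)\n",
              nrow(x$x), ncol(x$x),
              if (is.null(x$encoding_mode)) "compound-only" else
                paste0("fingerprint + ", x$encoding_mode, " encoding")))
  invisible(x)
}

#' Fit a pair-descriptor regression model
#'
#' Fits the learner described by `config` on a [build_pair_table()] result.
#' Forests are fit directly with the configured parameters; SVMs first run the
#' full `C x sigma` grid under an internal seeded `tune_folds`-fold
#' cross-validation minimizing RMSE, then refit at the selected point on all
#' rows.
#'
#' @param table a `pair_table` (or a list with `x` and `y`).
#' @param config a [model_config()].
#' @return An object of class `pgm_model` with the fitted learner, the config,
#'   standardization statistics (SVM), and for SVMs the grid-search results
#'   (`tuning`, data frame of `C, sigma, cv_rmse`) and chosen point.
#' @export
pgm_fit <- function(table, config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  x <- table$x; y <- table$y
  if (is.null(x) || nrow(x) == 0) stopf("no rows to fit")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  res <- if (config$learner == "rf") {
    fit <- ranger::ranger(x = x, y = y,
                          num.trees = config$num_trees,
                          mtry = resolve_mtry(config, ncol(x)),
                          min.node.size = config$min_node_size,
                          splitrule = "variance",
                          seed = child_seed(config$seed, "rf"),
                          num.threads = 1)
    list(fit = fit, tuning = NULL, best = NULL, center = NULL, scl = NULL)
  } else {
    if (nrow(x) < config$tune_folds) stopf("need >= %d rows for SVM tuning", config$tune_folds)
    ctr <- scl <- NULL
    xs <- x
    if (config$scale) {
      ctr <- colMeans(x)
      scl <- apply(x, 2, stats::sd)
      scl[scl == 0 | !is.finite(scl)] <- 1
      xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
    }
    folds <- with_seed(child_seed(config$seed, "svm_folds"),
                       sample(rep_len(seq_len(config$tune_folds), nrow(xs))))
    grid <- expand.grid(C = config$c_grid, sigma = config$sigma_grid)
    cv_rmse <- vapply(seq_len(nrow(grid)), function(g) {
      gamma <- 1 / (2 * grid$sigma[g]^2)
      errs <- vapply(seq_len(config$tune_folds), function(f) {
        tr <- folds != f
        if (!any(tr) || !any(!tr)) return(NA_real_)
        m <- e1071::svm(x = xs[tr, , drop = FALSE], y = y[tr],
                        type = "eps-regression", kernel = "radial",
                        cost = grid$C[g], gamma = gamma, scale = FALSE)
        pr <- stats::predict(m, xs[!tr, , drop = FALSE])
        sum((y[!tr] - pr)^2)
      }, numeric(1))
      sqrt(sum(errs, na.rm = TRUE) / nrow(xs))
    }, numeric(1))
    # ties break toward smaller C, then larger sigma
    ord <- order(cv_rmse, grid$C, -grid$sigma)
    best <- grid[ord[1], ]
    fit <- e1071::svm(x = xs, y = y, type = "eps-regression", kernel = "radial",
                      cost = best$C, gamma = 1 / (2 * best$sigma^2), scale = FALSE)
    list(fit = fit, tuning = cbind(grid, cv_rmse = cv_rmse), best = best,
         center = ctr, scl = scl)
  }
  structure(list(learner = config$learner, fit = res$fit, config = config,
                 n_features = ncol(x), feature_names = colnames(x),
                 tuning = res$tuning, best = res$best,
                 center = res$center, scl = res$scl,
                 n_train = nrow(x)),
            class = "pgm_model")
}

#' @export
print.pgm_model <- function(x, ...) {
  cat(sprintf("Pair-descriptor %s model: %d training pairs, %d descriptors\n",
              toupper(x$learner), x$n_train, x$n_features))
  if (x$learner == "rf") {
    cat(sprintf("  %d trees, mtry %d, min node size %d\n",
                x$config$num_trees, resolve_mtry(x$config, x$n_features),
                x$config$min_node_size))
  } else {
    cat(sprintf("  radial kernel, tuned C = %g, sigma = %g over %d grid points\n",
                x$best$C, x$best$sigma, nrow(x$tuning)))
  }
  invisible(x)
}

#' Predict pGI50 for pair descriptors
#'
#' @param object a `pgm_model`.
#' @param newdata a `pair_table` or a descriptor matrix with the training
#'   width.
#' @param ... unused.
#' @return Numeric vector of predictions, one per row.
#' @export
predict.pgm_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "pair_table")) newdata$x else as.matrix(newdata)
  if (ncol(x) != object$n_features) {
    stopf("descriptor width %d does not match training width %d",
          ncol(x), object$n_features)
  }
  colnames(x) <- object$feature_names
  if (object$learner == "rf") {
    as.numeric(stats::predict(object$fit, data = x, num.threads = 1)$predictions)
  } else {
    if (!is.null(object$center)) {
      x <- sweep(sweep(x, 2, object$center), 2, object$scl, "/")
    }
    as.numeric(stats::predict(object$fit, x))
  }
}
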