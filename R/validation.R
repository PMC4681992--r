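#' Build a cross-validation split plan for a panel
#'
#' Learning strategies over (compound, cell line) pairs:
#' \describe{
#'   \item{`tenfold_pgm`}{random partition of the *pairs* into `k` folds;
#'     compounds and cell lines may straddle folds (interpolation).}
#'   \item{`loco`}{one fold per cell line; its test set is all pairs of that
#'     line (extrapolation to new cell lines).}
#'   \item{`loto`}{one fold per tissue; all lines of the tissue are left out
#'     jointly (extrapolation to new tissues).}
#'   \item{`locco`}{one fold per chemical cluster; all pairs of the cluster's
#'     compounds are left out (extrapolation in chemical space). Requires a
#'     [delineate_clusters()] assignment.}
#'   \item{`family_qsar`}{same pair folds as `tenfold_pgm`; meant to be run
#'     with compound-only descriptors.}
#'   \item{`per_cellline_qsar`}{per cell line, an internal `k`-fold over that
#'     line's pairs; training is restricted to the same cell line
#'     (compound-only descriptors).}
#' }
#'
#' @param panel a `pgm_panel`.
#' @param strategy one of the strategies above.
#' @param clusters `cluster_assignment` (required for `locco`).
#' @param k number of folds for the pair-partition strategies.
#' @param seed integer seed.
#' @return An object of class `split_plan`: list with `strategy`, `folds`
#'   (list of `list(train, test, group)` index vectors into `panel$pairs`),
#'   `seed`.
#' @export
make_splits <- function(panel,
                        strategy = c("tenfold_pgm", "loco", "loto", "locco",
                                     "family_qsar", "per_cellline_qsar"),
                        clusters = NULL, k = 10L, seed = 1L) {
  stopifnot(inherits(panel, "pgm_panel"))
  strategy <- match.arg(strategy)
  p <- panel$pairs
  n <- nrow(p)
  folds <- switch(strategy,
    tenfold_pgm = ,
    family_qsar = {
      f <- with_seed(child_seed(seed, strategy), sample(rep_len(seq_len(k), n)))
      lapply(seq_len(k), function(i)
        list(train = which(f != i), test = which(f == i), group = as.character(i)))
    },
    loco = {
      lines <- sort(unique(p$cell_line_id))
      if (length(lines) < 2) stopf("leave-one-cell-line-out needs >= 2 cell lines")
      lapply(lines, function(l)
        list(train = which(p$cell_line_id != l), test = which(p$cell_line_id == l),
             group = l))
    },
    loto = {
      tis <- panel$tissues[p$cell_line_id]
      uts <- sort(unique(panel$tissues))
      if (length(uts) < 2) stopf("leave-one-tissue-out needs >= 2 tissues")
      lapply(uts, function(t)
        list(train = which(tis != t), test = which(tis == t), group = t))
    },
    locco = {
      if (!inherits(clusters, "cluster_assignment")) {
        stopf("strategy 'locco' requires a cluster_assignment")
      }
      cl <- clusters$compound_cluster[p$compound_id]
      if (anyNA(cl)) stopf("cluster assignment missing for some panel compounds")
      ucl <- sort(unique(cl))
      out <- lapply(ucl, function(cc)
        list(train = which(cl != cc), test = which(cl == cc),
             group = as.character(cc)))
      for (f in out) if (length(f$train) == 0) {
        stopf("cluster %s covers all compounds; empty training set", f$group)
      }
      out
    },
    per_cellline_qsar = {
      lines <- sort(unique(p$cell_line_id))
      out <- list()
      for (l in lines) {
        idx <- which(p$cell_line_id == l)
        kk <- min(k, length(idx))
        f <- with_seed(child_seed(seed, paste0("percl_", l)),
                       sample(rep_len(seq_len(kk), length(idx))))
        for (i in seq_len(kk)) {
          out[[length(out) + 1L]] <- list(train = idx[f != i], test = idx[f == i],
                                          group = l)
        }
      }
      out
    }
  )
  structure(list(strategy = strategy, folds = folds, seed = as.integer(seed),
                 n_pairs = n),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("Split plan '%s': %d folds over %d pairs\n",
              x$strategy, length(x$folds), x$n_pairs))
  invisible(x)
}

#' Run a learning strategy over a split plan
#'
#' Per fold: fit the configured model on the training pairs and predict the
#' test pairs. The identity-style encodings (`dirac`, `multitask`) cannot
#' describe unseen cell lines and are refused for `loco`/`loto` plans.
#'
#' @param panel a `pgm_panel`.
#' @param fp fingerprint matrix.
#' @param enc a `cell_encoding` or `NULL` (compound-only descriptors).
#' @param plan a [make_splits()] result.
#' @param config a [model_config()].
#' @return An object of class `strategy_result`: list with `predictions`
#'   (data frame `compound_id, cell_line_id, fold, group, y_obs, y_pred`),
#'   `per_fold` (metrics per fold), `pooled` (metrics over all predictions),
#'   `strategy`.
#' @export
run_strategy <- function(panel, fp, enc, plan, config = model_config()) {
  stopifnot(inherits(plan, "split_plan"))
  if (!is.null(enc) && encoding_mode(enc) %in% c("dirac", "multitask") &&
      plan$strategy %in% c("loco", "loto")) {
    stopf("the '%s' encoding cannot extrapolate to held-out cell lines (strategy '%s')",
          encoding_mode(enc), plan$strategy)
  }
  table <- build_pair_table(panel, fp, enc)
  preds <- vector("list", length(plan$folds))
  per_fold <- vector("list", length(plan$folds))
  for (i in seq_along(plan$folds)) {
    f <- plan$folds[[i]]
    cfg <- config
    cfg$seed <- child_seed(config$seed, paste0(plan$strategy, "_fold", i))
    fit <- pgm_fit(subset_pair_table(table, f$train), cfg)
    yp <- predict(fit, subset_pair_table(table, f$test))
    pr <- table$pairs[f$test, c("compound_id", "cell_line_id"), drop = FALSE]
    pr$fold <- i
    pr$group <- f$group
    pr$y_obs <- table$y[f$test]
    pr$y_pred <- yp
    preds[[i]] <- pr
    per_fold[[i]] <- cbind(fold = i, group = f$group,
                           panel_metrics(pr$y_obs, pr$y_pred))
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  structure(list(predictions = predictions,
                 per_fold = do.call(rbind, per_fold),
                 pooled = panel_metrics(predictions$y_obs, predictions$y_pred),
                 strategy = plan$strategy),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("Strategy '%s': %d predictions in %d folds\n",
              x$strategy, nrow(x$predictions), max(x$predictions$fold)))
  cat(sprintf("  pooled RMSE %.3f pGI50 units, R2_0 %.3f\n",
              x$pooled$rmse, x$pooled$r2_zero))
  invisible(x)
}

#' Groupwise performance summaries
#'
#' Recomputes the metrics on subsets of the pooled predictions grouped by cell
#' line, tissue or chemical cluster. Groups with fewer than two pairs report
#' the RMSE with `r2_zero` marked unavailable.
#'
#' @param result a [run_strategy()] result.
#' @param grouping `"cell_line"`, `"tissue"` or `"cluster"`.
#' @param panel the panel (needed for tissue labels).
#' @param clusters `cluster_assignment` (needed for `grouping = "cluster"`).
#' @return Data frame with one metrics row per group.
#' @export
groupwise_metrics <- function(result, grouping = c("cell_line", "tissue", "cluster"),
                              panel = NULL, clusters = NULL) {
  stopifnot(inherits(result, "strategy_result"))
  grouping <- match.arg(grouping)
  pr <- result$predictions
  g <- switch(grouping,
    cell_line = pr$cell_line_id,
    tissue = {
      if (is.null(panel)) stopf("grouping by tissue requires 'panel'")
      unname(panel$tissues[pr$cell_line_id])
    },
    cluster = {
      if (is.null(clusters)) stopf("grouping by cluster requires 'clusters'")
      as.character(clusters$compound_cluster[pr$compound_id])
    }
  )
  if (anyNA(g)) stopf("grouping label unavailable for some predictions")
  out <- do.call(rbind, lapply(split(seq_len(nrow(pr)), g), function(idx) {
    panel_metrics(pr$y_obs[idx], pr$y_pred[idx])
  }))
  data.frame(group = names(split(seq_len(nrow(pr)), g)), out, row.names = NULL)
}

#' Learning curve for one target cell line
#'
#' For every combination of a within-line and an across-line training
#' fraction, and for `n_rep` repetitions: train on that fraction of the target
#' cell line's pairs plus that fraction of the other lines' pairs, test on the
#' target line's held-out pairs, and average the test RMSE over repetitions.
#' With `across = 0` and compound-only descriptors this reduces to the
#' individual per-cell-line QSAR baseline.
#'
#' @param panel a `pgm_panel`.
#' @param fp,enc descriptors as in [run_strategy()].
#' @param target_cell_line cell line id to learn.
#' @param within_fractions fractions in `(0, 1)` of the target line's pairs
#'   used for training.
#' @param across_fractions fractions in `[0, 1]` of the other lines' pairs.
#' @param config a [model_config()].
#' @param n_rep repetitions per grid point.
#' @param seed integer seed.
#' @return Data frame `within, across, rep, n_train, rmse` plus the per-point
#'   mean in attribute-free long format (use `aggregate` for means).
#' @export
learning_curve <- function(panel, fp, enc, target_cell_line,
                           within_fractions = c(0.05, 0.1, 0.25, 0.5),
                           across_fractions = c(0, 0.1, 0.5, 1),
                           config = model_config(mtry = "sqrt"),
                           n_rep = 3L, seed = 1L) {
  stopifnot(inherits(panel, "pgm_panel"))
  p <- panel$pairs
  tgt <- which(p$cell_line_id == target_cell_line)
  if (length(tgt) == 0) stopf("cell line '%s' not in panel", target_cell_line)
  if (any(within_fractions <= 0 | within_fractions >= 1)) {
    stopf("'within_fractions' must lie in (0, 1): a full fraction leaves no test set")
  }
  if (any(across_fractions < 0 | across_fractions > 1)) {
    stopf("'across_fractions' must lie in [0, 1]")
  }
  other <- setdiff(seq_len(nrow(p)), tgt)
  table <- build_pair_table(panel, fp, enc)
  rows <- list()
  for (w in within_fractions) for (a in across_fractions) for (r in seq_len(n_rep)) {
    sd <- child_seed(seed, sprintf("curve_%g_%g_%d", w, a, r))
    pick <- with_seed(sd, {
      n_w <- max(1L, floor(w * length(tgt)))
      tr_w <- sample(tgt, n_w)
      tr_a <- if (a > 0 && length(other) > 0) sample(other, floor(a * length(other))) else integer(0)
      list(train = c(tr_w, tr_a), test = setdiff(tgt, tr_w))
    })
    cfg <- config
    cfg$seed <- sd
    fit <- pgm_fit(subset_pair_table(table, pick$train), cfg)
    yp <- predict(fit, subset_pair_table(table, pick$test))
    rows[[length(rows) + 1L]] <- data.frame(
      within = w, across = a, rep = r, n_train = length(pick$train),
      rmse = rmse(table$y[pick$test], yp))
  }
  do.call(rbind, rows)
}

#' Maximum and minimum achievable performance from experimental uncertainty
#'
#' Simulates the performance bounds implied by measurement noise. Per
#' repetition a sample `A` of `test_fraction` of the pairs is drawn from the
#' panel's mean pGI50 values; `B` adds each pair's experimental uncertainty
#' (the per-pair replicate sd, or the panel's default uncertainty where
#' absent), with a uniformly random half of the points getting the negative
#' sign. Maximum-performance metrics compare `A` with `B`; minimum-performance
#' metrics first permute `A` (destroying all signal) and then compare with
#' `B`.
#'
#' @param panel a `pgm_panel`.
#' @param n_rep repetitions (the reference protocol uses 1000).
#' @param test_fraction size of each sample as a fraction of the panel.
#' @param seed integer seed.
#' @return An object of class `bounds_result`: data frame with one row per
#'   repetition and columns `rmse_max, r2_max, rmse_min, r2_min`.
#' @export
performance_bounds <- function(panel, n_rep = 1000L, test_fraction = 0.1,
                               seed = 1L) {
  stopifnot(inherits(panel, "pgm_panel"))
  n_rep <- check_count(n_rep, "n_rep")
  check_fraction(test_fraction, "test_fraction", allow_zero = FALSE, allow_one = TRUE)
  y <- panel$pairs$y
  sig <- panel$pairs$sigma
  sig[is.na(sig)] <- panel$default_uncertainty
  if (anyNA(sig)) stopf("no per-pair uncertainty and no default uncertainty")
  m <- max(2L, floor(test_fraction * length(y)))
  out <- with_seed(child_seed(seed, "bounds"), {
    reps <- lapply(seq_len(n_rep), function(r) {
      idx <- sample.int(length(y), m)
      a <- y[idx]
      sgn <- rep(1, m)
      sgn[sample.int(m, floor(m / 2))] <- -1
      b <- a + sgn * sig[idx]
      mx <- panel_metrics(a, b)
      a_perm <- a[sample.int(m)]
      mn <- panel_metrics(a_perm, b)
      data.frame(rep = r, rmse_max = mx$rmse, r2_max = mx$r2_zero,
                 rmse_min = mn$rmse, r2_min = mn$r2_zero)
    })
    do.call(rbind, reps)
  })
  class(out) <- c("bounds_result", class(out))
  out
}

#' @export
summary.bounds_result <- function(object, ...) {
  s <- vapply(object[c("rmse_max", "r2_max", "rmse_min", "r2_min")],
              stats::median, numeric(1))
  cat(sprintf("Achievable performance over %d repetitions (medians):\n", nrow(object)))
  cat(sprintf("  max performance: RMSE %.3f, R2_0 %.3f\n", s["rmse_max"], s["r2_max"]))
  cat(sprintf("  min performance: RMSE %.3f, R2_0 %.3f\n", s["rmse_min"], s["r2_min"]))
  invisible(s)
}

#' y-scrambling control
#'
#' Permutes the targets among a random `ceiling(fraction * N)` subset of the
#' pairs (values conserved, assignments destroyed), reruns the ten-fold pair
#' interpolation strategy, and returns the pooled metrics. A model whose
#' apparent performance survives heavy scrambling is fitting chance
#' correlations.
#'
#' @param panel a `pgm_panel`.
#' @param fp,enc descriptors as in [run_strategy()].
#' @param fraction fraction of pairs whose targets are permuted, in `(0, 1]`.
#' @param config a [model_config()].
#' @param k folds of the interpolation strategy.
#' @param seed integer seed.
#' @return Pooled metrics data frame (see [panel_metrics()]).
#' @export
y_scramble <- function(panel, fp, enc, fraction, config = model_config(mtry = "sqrt"),
                       k = 10L, seed = 1L) {
  stopifnot(inherits(panel, "pgm_panel"))
  check_fraction(fraction, "fraction", allow_zero = FALSE, allow_one = TRUE)
  p <- panel$pairs
  n_perm <- ceiling(fraction * nrow(p))
  p$y <- with_seed(child_seed(seed, "scramble"), {
    idx <- sample.int(nrow(p), n_perm)
    y <- p$y
    y[idx] <- y[idx][sample.int(length(idx))]
    y
  })
  scrambled <- new_pgm_panel(p, panel$tissues, panel$default_uncertainty)
  plan <- make_splits(scrambled, "tenfold_pgm", k = k, seed = child_seed(seed, "scramble_folds"))
  run_strategy(scrambled, fp, enc, plan, config)$pooled
}
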