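#' Split a panel for conformal prediction
#'
#' Random pair-level three-way split: an external evaluation set (20% of the
#' pairs), and the remaining training portion split into a calibration set
#' (30% of it, i.e. 24% overall) and a proper training set (70% of it, 56%
#' overall). A warning (not an error) is raised if a compound or cell line is
#' absent from the proper training set.
#'
#' @param panel a `pgm_panel` with at least 50 pairs.
#' @param seed integer seed.
#' @param external_fraction,calibration_fraction split proportions (of the
#'   whole, and of the non-external part, respectively).
#' @return An object of class `conformal_split`: list of disjoint index
#'   vectors `external`, `calibration`, `proper` covering all pairs.
#' @export
conformal_split <- function(panel, seed = 1L, external_fraction = 0.2,
                            calibration_fraction = 0.3) {
  stopifnot(inherits(panel, "pgm_panel"))
  n <- nrow(panel$pairs)
  if (n < 50) stopf("conformal split needs >= 50 pairs, got %d", n)
  check_fraction(external_fraction, "external_fraction", allow_zero = FALSE)
  check_fraction(calibration_fraction, "calibration_fraction", allow_zero = FALSE)
  with_seed(child_seed(seed, "conformal_split"), {
    perm <- sample.int(n)
    n_ext <- round(external_fraction * n)
    n_cal <- round(calibration_fraction * (n - n_ext))
    external <- sort(perm[seq_len(n_ext)])
    calibration <- sort(perm[n_ext + seq_len(n_cal)])
    proper <- sort(perm[(n_ext + n_cal + 1):n])
  })
  p <- panel$pairs
  if (length(setdiff(unique(p$compound_id), p$compound_id[proper])) > 0 ||
      length(setdiff(unique(p$cell_line_id), p$cell_line_id[proper])) > 0) {
    warning("some compounds or cell lines are absent from the proper training set",
            call. = FALSE)
  }
  structure(list(external = external, calibration = calibration, proper = proper,
                 seed = as.integer(seed)),
            class = "conformal_split")
}

#' Fit a conformal predictor (point model, error model, calibration scores)
#'
#' Implements the split-conformal protocol for regression:
#' \enumerate{
#'   \item a seeded 10-fold cross-validation on the proper training set yields
#'     out-of-fold residuals for every proper-training pair;
#'   \item the point model is refit on the full proper training set;
#'   \item the error model is fit on the *absolute* out-of-fold residuals,
#'     so its prediction \eqn{\hat\rho} is a non-negative difficulty scale;
#'   \item each calibration pair is scored with the non-conformity
#'     \eqn{\alpha = |y - \hat y| / \max(\hat\rho, \rho_{floor})}, and the
#'     scores are sorted ascending.
#' }
#'
#' @param panel a `pgm_panel`.
#' @param fp,enc descriptors as in [build_pair_table()].
#' @param split a [conformal_split()] result.
#' @param config [model_config()] for both the point and the error model.
#'   The default uses a 100-tree forest with `mtry = "sqrt"`, the panel-scale
#'   configuration (see [model_config()]).
#' @param cv_folds folds of the residual-generating cross-validation.
#' @param rho_floor lower bound on the difficulty scale, pGI50 units;
#'   prevents division by near-zero for overconfident error models.
#' @return An object of class `conformal_predictor` with the two fitted
#'   models, the ascending calibration scores `alpha_calib`, `n_calib` and
#'   `rho_floor`.
#' @export
fit_conformal <- function(panel, fp, enc, split,
                          config = model_config(mtry = "sqrt"),
                          cv_folds = 10L, rho_floor = 1e-3) {
  stopifnot(inherits(split, "conformal_split"))
  if (rho_floor <= 0) stopf("'rho_floor' must be > 0")
  table <- build_pair_table(panel, fp, enc)
  proper <- subset_pair_table(table, split$proper)
  n_prop <- length(split$proper)
  folds <- with_seed(child_seed(config$seed, "conformal_cv"),
                     sample(rep_len(seq_len(cv_folds), n_prop)))
  resid <- numeric(n_prop)
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    cfg <- config
    cfg$seed <- child_seed(config$seed, paste0("conformal_cv_fold", f))
    fit <- pgm_fit(subset_pair_table(proper, which(tr)), cfg)
    yp <- predict(fit, subset_pair_table(proper, which(!tr)))
    resid[!tr] <- proper$y[!tr] - yp
  }
  cfg_pt <- config; cfg_pt$seed <- child_seed(config$seed, "conformal_point")
  point_model <- pgm_fit(proper, cfg_pt)
  err_table <- structure(list(x = proper$x, y = abs(resid), pairs = proper$pairs),
                         class = "pair_table")
  cfg_er <- config; cfg_er$seed <- child_seed(config$seed, "conformal_error")
  error_model <- pgm_fit(err_table, cfg_er)
  calib <- subset_pair_table(table, split$calibration)
  y_hat <- predict(point_model, calib)
  rho <- pmax(predict(error_model, calib), rho_floor)
  alpha <- sort(abs(calib$y - y_hat) / rho)
  structure(list(point_model = point_model, error_model = error_model,
                 alpha_calib = alpha, n_calib = length(alpha),
                 rho_floor = rho_floor, split = split, config = config),
            class = "conformal_predictor")
}

#' @export
print.conformal_predictor <- function(x, ...) {
  cat(sprintf("Conformal predictor: %d calibration scores (median %.3f), rho floor %g\n",
              x$n_calib, stats::median(x$alpha_calib), x$rho_floor))
  invisible(x)
}

#' Non-conformity threshold at a confidence level
#'
#' Returns the calibration score \eqn{\alpha_{1-\varepsilon}}: the `j`-th
#' smallest score with `j = floor(n_calib * (1 - epsilon))` (1-based).
#'
#' @param predictor a `conformal_predictor`.
#' @param epsilon tolerated error in `(0, 1)`; confidence is `1 - epsilon`.
#' @return Scalar threshold.
#' @export
alpha_at <- function(predictor, epsilon) {
  stopifnot(inherits(predictor, "conformal_predictor"))
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 1) {
    stopf("'epsilon' must lie in (0, 1)")
  }
  j <- floor(predictor$n_calib * (1 - epsilon))
  if (j < 1) stopf("confidence too low for calibration size %d", predictor$n_calib)
  predictor$alpha_calib[j]
}

#' Prediction intervals for pair descriptors
#'
#' Interval for each row: \eqn{\hat y \pm \alpha_{1-\varepsilon}\,
#' \max(\hat\rho, \rho_{floor})}.
#'
#' @param predictor a `conformal_predictor`.
#' @param table a `pair_table` (or descriptor matrix).
#' @param epsilon tolerated error; confidence is `1 - epsilon`.
#' @return Data frame `point, half_width, lower, upper, confidence`.
#' @export
predict_interval <- function(predictor, table, epsilon) {
  a <- alpha_at(predictor, epsilon)
  point <- predict(predictor$point_model, table)
  rho <- pmax(predict(predictor$error_model, table), predictor$rho_floor)
  hw <- a * rho
  data.frame(point = point, half_width = hw,
             lower = point - hw, upper = point + hw,
             confidence = 1 - epsilon)
}

#' @export
predict.conformal_predictor <- function(object, newdata, epsilon = 0.2, ...) {
  predict_interval(object, newdata, epsilon)
}

#' Empirical coverage of conformal intervals on an external set
#'
#' For each tolerated error in the grid, the fraction of external pairs whose
#' observed value lies inside the predicted interval, plus the Spearman rank
#' correlation between the confidence levels and the coverages.
#'
#' @param predictor a `conformal_predictor`.
#' @param table a `pair_table` for the external pairs.
#' @param y_obs observed pGI50 values for the external pairs.
#' @param epsilon_grid tolerated errors; default confidence levels 0.50..0.95.
#' @return List with `table` (data frame `confidence, coverage, n`) and
#'   `spearman`.
#' @export
validate_coverage <- function(predictor, table, y_obs,
                              epsilon_grid = seq(0.5, 0.05, by = -0.05)) {
  n <- if (inherits(table, "pair_table")) nrow(table$x) else nrow(table)
  if (n == 0) stopf("empty external set")
  if (length(y_obs) != n) stopf("'y_obs' length must match the external table")
  point <- predict(predictor$point_model, table)
  rho <- pmax(predict(predictor$error_model, table), predictor$rho_floor)
  rows <- lapply(epsilon_grid, function(eps) {
    hw <- alpha_at(predictor, eps) * rho
    data.frame(confidence = 1 - eps,
               coverage = mean(y_obs >= point - hw & y_obs <= point + hw),
               n = n)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$confidence), ]
  rownames(tab) <- NULL
  sp <- suppressWarnings(stats::cor(tab$confidence, tab$coverage, method = "spearman"))
  list(table = tab, spearman = sp)
}
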