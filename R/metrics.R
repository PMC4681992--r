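#' Root-mean-square error
#'
#' \eqn{RMSE = \sqrt{\sum_i (y_i - \hat y_i)^2 / N}}, in pGI50 units.
#'
#' @param observed,predicted numeric vectors of equal length >= 1.
#' @return Non-negative scalar.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stopf("length mismatch")
  if (length(observed) < 1) stopf("need at least one observation")
  sqrt(mean((observed - predicted)^2))
}

#' Coefficient of determination through the origin
#'
#' \eqn{R^2_0} compares the observations with the rescaled predictions
#' \eqn{\hat y^{r0}_i = s\,\hat y_i}, where the slope of the
#' observed-on-predicted regression through the origin is
#' \eqn{s = \sum_i y_i \hat y_i / \sum_i \hat y_i^2}:
#' \deqn{R^2_0 = 1 - \frac{\sum_i (y_i - s \hat y_i)^2}{\sum_i (y_i - \bar y)^2}.}
#' It is invariant to positive rescaling of the predictions and can be
#' arbitrarily negative.
#'
#' @param observed,predicted numeric vectors, length >= 2; `observed` must not
#'   be constant and `sum(predicted^2)` must be positive.
#' @return Scalar `<= 1`.
#' @export
r2_zero <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stopf("length mismatch")
  if (length(observed) < 2) stopf("need at least two observations")
  denom_pred <- sum(predicted^2)
  if (denom_pred <= 0) stopf("sum of squared predictions is zero; slope undefined")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stopf("constant observations; R2_0 undefined")
  s <- sum(observed * predicted) / denom_pred
  1 - sum((observed - s * predicted)^2) / ss_tot
}

#' Point-prediction metrics for a set of pairs
#'
#' Bundles [rmse()] and [r2_zero()] (with its origin slope `s`) for one
#' prediction set; `r2_zero` and `s` are `NA` where undefined (fewer than two
#' points or constant observations).
#'
#' @inheritParams rmse
#' @return A one-row data frame `n, rmse, r2_zero, s`.
#' @export
panel_metrics <- function(observed, predicted) {
  r2 <- s <- NA_real_
  if (length(observed) >= 2 && stats::sd(observed) > 0 && sum(predicted^2) > 0) {
    s <- sum(observed * predicted) / sum(predicted^2)
    r2 <- r2_zero(observed, predicted)
  }
  data.frame(n = length(observed), rmse = rmse(observed, predicted),
             r2_zero = r2, s = s)
}
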