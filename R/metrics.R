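#' Root mean square error
#'
#' @param actual,predicted equal-length finite numeric vectors.
#' @return `sqrt(mean((actual - predicted)^2))`, in the data's units
#'   (micrograms per cubic metre for pollutant concentrations).
#' @export
rmse <- function(actual, predicted) {
  check_pair(actual, predicted)
  sqrt(mean((actual - predicted)^2))
}

#' Relative root mean square error
#'
#' RMSE divided by the mean of the actual values: a dimensionless, scale-free
#' accuracy measure that is comparable across pollutants with very different
#' concentration ranges. Undefined (an error) when the actual mean is not
#' positive; pollutant concentrations are non-negative, so a non-positive
#' mean indicates a degenerate evaluation set rather than a meaningful score.
#'
#' @inheritParams rmse
#' @return Dimensionless RRMSE `>= 0`.
#' @export
rrmse <- function(actual, predicted) {
  check_pair(actual, predicted)
  m <- mean(actual)
  if (m <= 0) stop_metric("RRMSE undefined: mean(actual) <= 0")
  rmse(actual, predicted) / m
}

check_pair <- function(actual, predicted) {
  if (length(actual) == 0 || length(actual) != length(predicted)) {
    stop_contract("`actual` and `predicted` must have equal nonzero length")
  }
  if (!all(is.finite(actual)) || !all(is.finite(predicted))) {
    stop_contract("`actual` and `predicted` must be finite")
  }
}

#' Relative error reduction, in integer percent
#'
#' `100 * (1 - rrmse_new / rrmse_base)`, rounded half-away-from-zero to the
#' nearest integer percent (the convention of integer summary tables).
#' Negative values mean the new model is worse than the baseline.
#'
#' @param rrmse_base baseline RRMSE (> 0).
#' @param rrmse_new comparison RRMSE.
#' @return Integer percent.
#' @examples
#' relative_reduction(0.69, 0.31) # 55
#' @export
relative_reduction <- function(rrmse_base, rrmse_new) {
  if (rrmse_base <= 0) stop_domain("`rrmse_base` must be > 0")
  x <- 100 * (1 - rrmse_new / rrmse_base)
  as.integer(trunc(x + sign(x) * 0.5)) # round half away from zero
}

#' Evaluate a set of horizon forecasts
#'
#' Pools every horizon point of every window into one sequence before
#' computing RMSE and RRMSE (a single sum over the evaluation horizon, not a
#' per-window average of scores).
#'
#' @param actual,forecast matrices of matching shape (windows x horizon), or
#'   equal-length vectors.
#' @return A `metric_report`: list with `rmse`, `rrmse`, `n_points`,
#'   `mean_actual`.
#' @export
evaluate_forecasts <- function(actual, forecast) {
  a <- as.vector(as.matrix(actual))
  f <- as.vector(as.matrix(forecast))
  check_pair(a, f)
  structure(
    list(rmse = rmse(a, f), rrmse = rrmse(a, f),
         n_points = length(a), mean_actual = mean(a)),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> RMSE %.4f ug/m^3 | RRMSE %.4f | n = %d (mean actual %.3f)\n",
              x$rmse, x$rrmse, x$n_points, x$mean_actual))
  invisible(x)
}
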