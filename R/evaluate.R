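#' Pearson correlation and RMSE between predictions and observations
#'
#' If either vector is constant the correlation is undefined; it is reported
#' as `NA` with a warning rather than silently imputed as 0.
#'
#' @param predictions,actual numeric vectors of equal length (>= 2).
#' @return list with elements `corr` and `rmse`.
#' @export
evaluate_predictions <- function(predictions, actual) {
  predictions <- as.numeric(predictions)
  actual <- as.numeric(actual)
  if (length(predictions) != length(actual)) stop("length mismatch")
  if (length(actual) < 2) stop("need at least 2 observations")
  rmse <- sqrt(mean((predictions - actual)^2))
  if (sd(predictions) == 0 || sd(actual) == 0) {
    warning("correlation undefined for constant vector; reported as NA")
    corr <- NA_real_
  } else {
    corr <- cor(predictions, actual)
  }
  list(corr = corr, rmse = rmse)
}
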