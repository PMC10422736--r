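#' Regression metrics for reaction-outcome predictions
#'
#' Computes the three evaluation metrics used throughout the package, in the
#' original outcome units: `r2`, the squared Pearson correlation between
#' predictions and observations (the convention of the yield-prediction
#' literature); `mae`, the mean absolute error; and `rmse`, the root mean
#' squared error. The coefficient of determination (`r2_cod`,
#' `1 - SS_res/SS_tot`) is reported alongside for reference; for a
#' well-calibrated model the two R-squared notions agree.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return A one-row tibble with columns `r2`, `mae`, `rmse`, `r2_cod`, `n`.
#' @examples
#' eval_metrics(c(0, 1, 2), c(0, 1, 5))
#' @export
eval_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have equal length.")
  }
  if (length(observed) < 2L) abort("Need at least two observations.")
  if (!all(is.finite(observed)) || !all(is.finite(predicted))) {
    abort("Metrics require finite observations and predictions.")
  }
  if (sd(observed) == 0) {
    abort("Observations have zero variance; R-squared is undefined.",
          class = "rxngraph_degenerate_data")
  }
  err <- predicted - observed
  r2 <- if (sd(predicted) == 0) 0 else cor(observed, predicted)^2
  tibble::tibble(
    r2 = r2,
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    r2_cod = 1 - sum(err^2) / sum((observed - mean(observed))^2),
    n = length(observed)
  )
}
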