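#' Z-score scaler for reaction outcomes
#'
#' Outcomes are standardized before regression, `x_hat = (x - mu) / sigma`,
#' with `mu` and `sigma` the mean and standard deviation of the training
#' outcomes (population form, i.e. the `n` denominator, the usual machine
#' learning convention: `c(0, 10)` gives `mu = 5`, `sigma = 5`); predictions
#' are mapped back to original units with the inverse transform.
#'
#' @param outcomes Numeric vector of training outcomes (length >= 2, nonzero
#'   variance).
#' @return A list of class `rxn_scaler` with elements `mu` and `sigma`.
#' @examples
#' sc <- fit_scaler(c(0, 10))
#' scaler_transform(sc, c(0, 5, 10))
#' @export
fit_scaler <- function(outcomes) {
  outcomes <- as.numeric(outcomes)
  if (length(outcomes) < 2L || anyNA(outcomes) || !all(is.finite(outcomes))) {
    abort("Need >= 2 finite outcomes to fit the scaler.")
  }
  sigma <- sqrt(mean((outcomes - mean(outcomes))^2))
  if (!is.finite(sigma) || sigma <= 0) {
    abort("Outcomes have zero variance; z-score normalization is undefined.",
          class = "rxngraph_degenerate_data")
  }
  structure(list(mu = mean(outcomes), sigma = sigma), class = "rxn_scaler")
}

#' @rdname fit_scaler
#' @param scaler An `rxn_scaler`.
#' @param x Numeric vector to (inverse-)transform.
#' @export
scaler_transform <- function(scaler, x) (x - scaler$mu) / scaler$sigma

#' @rdname fit_scaler
#' @export
scaler_inverse <- function(scaler, x) x * scaler$sigma + scaler$mu
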