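#' Tidy per-fold cross-validation metrics
#'
#' @param x An `rxn_cv` object.
#' @param ... Unused.
#' @return A tibble with one row per fold and columns `fold`, `r2`, `mae`,
#'   `rmse`, `r2_cod`, `n`.
#' @export
tidy.rxn_cv <- function(x, ...) x$metrics

#' One-row cross-validation summary (mean and SD across folds)
#'
#' @param x An `rxn_cv` object.
#' @param ... Unused.
#' @return A one-row tibble with `<metric>_mean` and `<metric>_sd` columns
#'   plus `k`.
#' @export
glance.rxn_cv <- function(x, ...) {
  wide <- x$summary |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = c("mean", "sd"),
                       names_glue = "{metric}_{.value}")
  dplyr::mutate(wide, k = x$fold_plan$k)
}

#' Tidy the training log of a fitted model
#'
#' @param x An `rxn_model`.
#' @param ... Unused.
#' @return The per-epoch tibble of train and validation losses (normalized
#'   outcome scale).
#' @export
tidy.rxn_model <- function(x, ...) x$log

#' One-row fit summary
#'
#' @param x An `rxn_model`.
#' @param ... Unused.
#' @return A one-row tibble with the epochs run, best epoch, best validation
#'   loss and model dimensions.
#' @export
glance.rxn_model <- function(x, ...) {
  tibble::tibble(
    epochs_run = nrow(x$log),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    hidden_size = x$config$hidden_size,
    depth = x$config$depth,
    aggregation = x$config$aggregation
  )
}

#' Observed-versus-predicted plot for a cross-validation run
#'
#' @param object An `rxn_cv` object.
#' @param ... Unused.
#' @return A ggplot: test-set predictions against observations, coloured by
#'   fold, with the identity line.
#' @export
autoplot.rxn_cv <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted,
                               colour = factor(.data$fold))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Observed outcome", y = "Predicted outcome",
                  colour = "Fold") +
    ggplot2::theme_minimal()
}

#' Training-curve plot for a fitted model
#'
#' @param object An `rxn_model`.
#' @param ... Unused.
#' @return A ggplot of per-epoch train and validation loss.
#' @export
autoplot.rxn_model <- function(object, ...) {
  long <- tidyr::pivot_longer(object$log, c("train_loss", "val_loss"),
                              names_to = "set", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "MSE (normalized outcome)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
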