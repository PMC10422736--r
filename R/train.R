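# Training protocol: z-score the training outcomes, minimize mean squared
# error on the normalized scale with Adam, monitor a held-out validation
# split every epoch and stop early when it no longer improves, then restore
# the best-validation parameters.

ENCODER_PARAM_NAMES <- c("Wi_n", "bi_n", "Wi_e", "bi_e", "Wc", "bc", "W",
                         "Wo", "bo", "Wz", "Uz", "bz", "Wr", "Ur", "br",
                         "Wh", "Uh", "bh")

# Canonicalize every SMILES cell of the component columns; returns a
# character matrix (n x n_components) plus the graph list for the unique
# molecules.
prepare_components <- function(data, schema) {
  comp <- as.matrix(data[schema$components])
  can <- vapply(as.vector(comp), function(s) canonical_smiles(s), character(1),
                USE.NAMES = FALSE)
  comp_can <- matrix(can, nrow = nrow(comp), dimnames = list(NULL, colnames(comp)))
  uniq <- unique(as.vector(comp_can))
  graphs <- setNames(lapply(uniq, build_graph), uniq)
  list(comp_can = comp_can, graphs = graphs)
}

# One forward + backward pass on a set of rows. Returns the scalar loss and
# the full gradient list (encoder + head). Internal; also exercised directly
# by the finite-difference gradient test.
forward_backward <- function(params, config, graphs, comp_can, oh, y_norm,
                             rows) {
  sub <- comp_can[rows, , drop = FALSE]
  uniq <- unique(as.vector(sub))
  bg <- batch_graphs(graphs[uniq])
  fwd <- encoder_forward(bg, params, config, keep_cache = TRUE)
  emb <- fwd$embeddings
  rownames(emb) <- uniq
  asm <- assemble_reactions(emb, sub, oh[rows, , drop = FALSE], config)
  hf <- head_forward(asm$U, params)
  resid <- hf$yhat - y_norm[rows]
  loss <- mean(resid^2)
  if (!is.finite(loss)) {
    abort("Training diverged: non-finite loss. Try a smaller learning rate.",
          class = "rxngraph_divergence")
  }
  dY <- 2 * resid / length(rows)
  hb <- head_backward(dY, hf, params)
  dEmb <- disperse_dU(hb$dU, asm, config, n_unique = length(uniq))
  genc <- encoder_backward(dEmb, fwd$cache, params, config)
  grads <- c(genc, hb[c("W1", "b1", "W2", "b2")])
  list(loss = loss, grads = grads)
}

predict_rows <- function(params, config, graphs, comp_can, oh, rows) {
  sub <- comp_can[rows, , drop = FALSE]
  uniq <- unique(as.vector(sub))
  bg <- batch_graphs(graphs[uniq])
  emb <- encoder_forward(bg, params, config)$embeddings
  rownames(emb) <- uniq
  asm <- assemble_reactions(emb, sub, oh[rows, , drop = FALSE], config)
  head_forward(asm$U, params)$yhat
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) if (is.matrix(p)) p * 0 else numeric(length(p)))
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

#' Fit the reaction-outcome regression model
#'
#' Trains the full pipeline — message-passing encoder, reaction-vector
#' aggregation, one-hot blocks for categorical components, dense head — on a
#' reaction table. Outcomes are z-scored using the gradient-update training
#' rows only; a validation split (by default 20% of the supplied data) is
#' monitored for early stopping and the parameters from the best-validation
#' epoch are returned.
#'
#' @param data A data frame with the columns named by `schema`.
#' @param schema An [rxn_schema()].
#' @param config An [rxn_config()].
#' @param val_fraction Fraction of rows held out for validation when
#'   `indices` is not given. `0` disables early stopping.
#' @param indices Optional list with integer vectors `train` and `val` to
#'   control the split explicitly (used by [cv_rxn()]).
#' @return An object of class `rxn_model` with elements `params`, `config`,
#'   `schema`, `scaler`, `vocab`, `log` (per-epoch train/validation losses),
#'   `best_epoch` and `indices`.
#' @seealso [predict.rxn_model()], [cv_rxn()]
#' @export
train_rxn <- function(data, schema, config, val_fraction = 0.2,
                      indices = NULL) {
  stopifnot(inherits(schema, "rxn_schema"), inherits(config, "rxn_config"))
  check_schema(data, schema)
  data <- as.data.frame(data)
  n <- nrow(data)
  if (n < 10L) abort("Need at least 10 reactions to train.")
  seeds <- derive_seeds(config$seed, 3L)

  if (is.null(indices)) {
    all_rows <- seq_len(n)
    n_val <- floor(val_fraction * n)
    val <- if (n_val > 0L) {
      sort(with_seed_local(seeds[[1]], sample(all_rows, n_val)))
    } else integer(0)
    indices <- list(train = setdiff(all_rows, val), val = val)
  }
  train_rows <- indices$train
  val_rows <- indices$val
  if (length(intersect(train_rows, val_rows)) > 0L) {
    abort("Train and validation indices overlap.")
  }

  y <- as.numeric(data[[schema$outcome]])
  if (!all(is.finite(y[c(train_rows, val_rows)]))) {
    abort("Outcome column contains non-finite values.")
  }
  scaler <- fit_scaler(y[train_rows])
  y_norm <- scaler_transform(scaler, y)

  vocab <- build_vocab(data[train_rows, , drop = FALSE], schema)
  oh <- onehot_block(data, vocab)
  prep <- prepare_components(data, schema)

  params <- init_params(config, reaction_width(config, schema, vocab))
  opt <- adam_init(params)
  epoch_seeds <- with_seed_local(seeds[[2]],
                                 sample.int(.Machine$integer.max - 1L,
                                            config$epochs))

  best_params <- params
  best_val <- Inf
  best_epoch <- 0L
  stall <- 0L
  log <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    order_rows <- with_seed_local(epoch_seeds[[epoch]], sample(train_rows))
    batches <- split(order_rows,
                     ceiling(seq_along(order_rows) / config$batch_size))
    epoch_loss <- 0
    for (b in batches) {
      fb <- forward_backward(params, config, prep$graphs, prep$comp_can, oh,
                             y_norm, b)
      epoch_loss <- epoch_loss + fb$loss * length(b)
      upd <- adam_step(params, fb$grads, opt, config$learning_rate)
      params <- upd$params
      opt <- upd$state
    }
    train_loss <- epoch_loss / length(train_rows)

    val_loss <- NA_real_
    if (length(val_rows) > 0L) {
      vp <- predict_rows(params, config, prep$graphs, prep$comp_can, oh,
                         val_rows)
      val_loss <- mean((vp - y_norm[val_rows])^2)
    }
    log[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = train_loss,
                                   val_loss = val_loss)

    if (length(val_rows) > 0L) {
      if (is.finite(val_loss) && val_loss < best_val) {
        best_val <- val_loss
        best_params <- params
        best_epoch <- epoch
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall > config$patience) break
      }
    } else {
      best_params <- params
      best_epoch <- epoch
    }
  }

  structure(list(
    params = best_params,
    config = config,
    schema = schema,
    scaler = scaler,
    vocab = vocab,
    log = dplyr::bind_rows(log[!vapply(log, is.null, logical(1))]),
    best_epoch = best_epoch,
    best_val_loss = if (is.finite(best_val)) best_val else NA_real_,
    indices = indices
  ), class = "rxn_model")
}

#' @export
print.rxn_model <- function(x, ...) {
  cat("<rxn_model> ", x$config$aggregation, "-aggregated, d = ",
      x$config$hidden_size, ", depth = ", x$config$depth, "\n", sep = "")
  cat("  components:", paste(x$schema$components, collapse = ", "), "\n")
  cat("  trained ", nrow(x$log), " epochs (best epoch ", x$best_epoch, ")\n",
      sep = "")
  invisible(x)
}

#' Predict reaction outcomes for new reactions
#'
#' @param object A fitted [train_rxn()] model.
#' @param newdata Data frame with the schema's component (and categorical)
#'   columns.
#' @param ... Unused.
#' @return A tibble with one column `.pred`, predictions in original outcome
#'   units.
#' @export
predict.rxn_model <- function(object, newdata, ...) {
  check_schema(newdata, object$schema, need_outcome = FALSE)
  newdata <- as.data.frame(newdata)
  oh <- onehot_block(newdata, object$vocab)
  prep <- prepare_components(newdata, object$schema)
  yhat <- predict_rows(object$params, object$config, prep$graphs,
                       prep$comp_can, oh, seq_len(nrow(newdata)))
  tibble::tibble(.pred = scaler_inverse(object$scaler, yhat))
}

#' k-fold cross-validation of the reaction model
#'
#' Partitions the dataset into `k` disjoint test folds; for each fold the
#' model is trained on the remaining rows (with an inner validation split
#' for early stopping, the outcome scaler fit on the gradient-update rows
#' only) and evaluated on the held-out test fold in original outcome units.
#'
#' @inheritParams train_rxn
#' @param k Number of folds.
#' @param val_fraction Fraction of each fold's training portion held out for
#'   validation.
#' @return An object of class `rxn_cv`: list with `metrics` (per-fold
#'   tibble), `summary` (mean and standard deviation per metric),
#'   `predictions` (per-row observed/predicted tibble), `fold_plan`, and
#'   `config`.
#' @seealso [tidy.rxn_cv()], [glance.rxn_cv()], [autoplot.rxn_cv()]
#' @export
cv_rxn <- function(data, schema, config, k = 5L, val_fraction = 0.2) {
  data <- as.data.frame(data)
  check_schema(data, schema)
  plan <- make_folds(nrow(data), k, val_fraction, seed = config$seed)
  y <- as.numeric(data[[schema$outcome]])
  res <- lapply(seq_len(k), function(i) {
    f <- plan$folds[[i]]
    fit <- train_rxn(data, schema, config,
                     indices = list(train = f$train, val = f$val))
    pred <- predict(fit, data[f$test, , drop = FALSE])$.pred
    m <- eval_metrics(y[f$test], pred)
    list(metrics = dplyr::mutate(m, fold = i, .before = 1),
         predictions = tibble::tibble(fold = i, row = f$test,
                                      observed = y[f$test], predicted = pred))
  })
  metrics <- dplyr::bind_rows(lapply(res, `[[`, "metrics"))
  summary <- metrics |>
    tidyr::pivot_longer(c("r2", "mae", "rmse", "r2_cod"),
                        names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
  structure(list(
    metrics = metrics,
    summary = summary,
    predictions = dplyr::bind_rows(lapply(res, `[[`, "predictions")),
    fold_plan = plan,
    config = config,
    schema = schema
  ), class = "rxn_cv")
}

#' @export
print.rxn_cv <- function(x, ...) {
  cat("<rxn_cv> ", x$fold_plan$k, "-fold cross-validation (",
      x$config$aggregation, ", d = ", x$config$hidden_size, ")\n", sep = "")
  s <- x$summary
  for (m in c("r2", "mae", "rmse")) {
    row <- s[s$metric == m, ]
    cat(sprintf("  %-5s %.3f ± %.3f\n", row$metric, row$mean, row$sd))
  }
  invisible(x)
}
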