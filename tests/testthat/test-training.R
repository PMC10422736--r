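test_that("z-score scaler matches the closed form and round-trips", {
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  sc <- fit_scaler(c(0, 10))
  expect_equal(sc$mu, 5)
  expect_equal(sc$sigma, 5)
  expect_equal(scaler_transform(sc, c(0, 10)), c(-1, 1))
  set.seed(1)
  x <- rnorm(50, 3, 7)
  sc <- fit_scaler(x)
  expect_equal(mean(scaler_transform(sc, x)), 0, tolerance = 1e-9)
  expect_equal(pop_sd(scaler_transform(sc, x)), 1, tolerance = 1e-9)
  expect_equal(scaler_inverse(sc, scaler_transform(sc, x)), x,
               tolerance = 1e-9)
  expect_error(fit_scaler(rep(2, 5)), class = "rxngraph_degenerate_data")
})

test_that("fold plans partition the data with the 80:20:inner-20 geometry", {
  fp <- make_folds(100, k = 10, val_fraction = 0.2, seed = 3)
  tests <- lapply(fp$folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:100)
  expect_true(all(lengths(tests) == 10L))
  for (f in fp$folds) {
    expect_length(intersect(f$train, f$val), 0L)
    expect_length(intersect(f$train, f$test), 0L)
    expect_length(intersect(f$val, f$test), 0L)
  }
  # k=5 on 100 rows: test 20, training portion 80 -> val 16, train 64
  fp5 <- make_folds(100, k = 5, val_fraction = 0.2, seed = 1)
  expect_equal(lengths(fp5$folds[[1]])[c("train", "val", "test")],
               c(train = 64L, val = 16L, test = 20L))
  # k=5 on 1558 rows: test sizes 311 or 312
  fp1558 <- make_folds(1558, k = 5, seed = 2)
  sizes <- vapply(fp1558$folds, function(f) length(f$test), integer(1))
  expect_true(all(sizes %in% c(311L, 312L)))
  expect_equal(sum(sizes), 1558L)
  # reproducibility
  expect_identical(make_folds(50, 5, seed = 9), make_folds(50, 5, seed = 9))
  expect_error(make_folds(3, 5))
})

test_that("evaluation metrics match hand arithmetic and scale laws", {
  m <- eval_metrics(c(0, 1, 2), c(0, 1, 2))
  expect_equal(c(m$r2, m$mae, m$rmse), c(1, 0, 0))
  m <- eval_metrics(c(0, 1, 2), c(0, 1, 5))
  expect_equal(m$mae, 1)
  expect_equal(m$rmse, sqrt(3))
  # Pearson-based R2 is scale-invariant; errors are not
  obs <- c(0.1, 0.4, 0.9, 0.3)
  pred <- c(0.2, 0.5, 0.7, 0.2)
  m1 <- eval_metrics(obs, pred)
  m2 <- eval_metrics(obs, pred * 2)
  expect_equal(m1$r2, m2$r2)
  expect_gt(m2$mae, m1$mae)
  expect_gte(m1$rmse, m1$mae)
  expect_error(eval_metrics(1:3, 1:2))
  expect_error(eval_metrics(rep(1, 3), 1:3),
               class = "rxngraph_degenerate_data")
})

test_that("rmse is never below mae across random prediction sets", {
  set.seed(11)
  for (i in 1:20) {
    obs <- rnorm(30)
    pred <- obs + rnorm(30, sd = runif(1, 0.01, 2))
    m <- eval_metrics(obs, pred)
    expect_gte(m$rmse, m$mae)
  }
})

test_that("training memorizes a small noiseless dataset", {
  d <- generate_reactions(20, seed = 5, noise_sd = 0)
  cfg <- rxn_config(hidden_size = 32L, depth = 2L, seed = 2L,
                    learning_rate = 5e-3, batch_size = 10L, epochs = 300L,
                    patience = 300L)
  fit <- train_rxn(d, synthetic_schema(), cfg, val_fraction = 0)
  m <- eval_metrics(d$ratio, predict(fit, d)$.pred)
  expect_gte(m$r2, 0.99)
})

test_that("the outcome scaler is fit without validation or test leakage", {
  d <- generate_reactions(60, seed = 8)
  cfg <- rxn_config(hidden_size = 8L, depth = 1L, seed = 4L, epochs = 2L)
  fit <- train_rxn(d, synthetic_schema(), cfg, val_fraction = 0.2)
  train_rows <- fit$indices$train
  expect_equal(fit$scaler$mu, mean(d$ratio[train_rows]))
  expect_equal(fit$scaler$sigma,
               sqrt(mean((d$ratio[train_rows] - mean(d$ratio[train_rows]))^2)))
  expect_false(isTRUE(all.equal(fit$scaler$mu, mean(d$ratio))))
})

test_that("identical seeds give identical training trajectories", {
  d <- generate_reactions(40, seed = 3)
  cfg <- rxn_config(hidden_size = 8L, depth = 2L, seed = 21L, epochs = 4L,
                    patience = 4L)
  f1 <- train_rxn(d, synthetic_schema(), cfg)
  f2 <- train_rxn(d, synthetic_schema(), cfg)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$params, f2$params)
})

test_that("early stopping with zero patience stops at the first stall", {
  d <- generate_reactions(40, seed = 6)
  cfg <- rxn_config(hidden_size = 8L, depth = 1L, seed = 10L, epochs = 400L,
                    patience = 0L)
  fit <- train_rxn(d, synthetic_schema(), cfg)
  log <- tidy(fit)
  n_run <- nrow(log)
  # with zero patience the run must end at the first epoch that fails to
  # improve on the running best (or exhaust the epoch budget improving
  # every single time, which a 400-epoch budget rules out in practice)
  expect_lt(n_run, 400L)
  # every epoch before the stop improved strictly, the last one did not
  expect_true(all(diff(log$val_loss[seq_len(n_run - 1L)]) < 0))
  expect_gte(log$val_loss[n_run], log$val_loss[n_run - 1L])
  expect_equal(fit$best_epoch, n_run - 1L)
})

test_that("cross-validation reports one metric row per fold plus a summary", {
  d <- generate_reactions(60, seed = 12)
  cfg <- rxn_config(hidden_size = 8L, depth = 1L, seed = 5L, epochs = 3L,
                    patience = 3L, aggregation = "sum")
  cv <- cv_rxn(d, synthetic_schema(), cfg, k = 3L)
  expect_equal(nrow(cv$metrics), 3L)
  expect_setequal(cv$metrics$fold, 1:3)
  # summary recomputes from per-fold values
  for (met in c("r2", "mae", "rmse")) {
    row <- cv$summary[cv$summary$metric == met, ]
    expect_equal(row$mean, mean(cv$metrics[[met]]), tolerance = 1e-12)
    expect_equal(row$sd, sd(cv$metrics[[met]]), tolerance = 1e-12)
  }
  # persisted predictions cover each test fold exactly once
  expect_equal(sort(cv$predictions$row), 1:60)
  # tidy/glance accessors
  expect_equal(tidy(cv), cv$metrics)
  expect_true(all(c("r2_mean", "r2_sd", "k") %in% names(glance(cv))))
})

test_that("run configs round-trip through YAML and reject unknown keys", {
  path <- tempfile(fileext = ".yml")
  cfg <- rxn_config(hidden_size = 16L, depth = 2L, seed = 4L)
  schema <- synthetic_schema(include_product = FALSE)
  write_config_echo(cfg, schema, cv = list(k = 5, val_fraction = 0.2),
                    path = path)
  rc <- read_run_config(path)
  expect_equal(rc$config, cfg)
  expect_equal(rc$schema, schema)
  expect_equal(rc$cv$k, 5)
  bad <- tempfile(fileext = ".yml")
  writeLines("model:\n  hidden_size: 8\n  typo_key: 3", bad)
  expect_error(read_run_config(bad), class = "rxngraph_config_error")
})
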