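tiny_arch <- function(n_outputs = 4L) {
  arch_spec(list(c(4, 3), c(8, 3)), n_outputs = n_outputs, input_size = 32)
}

test_that("training configuration validates its invariants", {
  expect_error(train_config(max_epochs = 10, patience = 10), "patience")
  expect_error(train_config(learning_rate = 0))
  cfg <- train_config(max_epochs = 5, patience = 0)
  expect_equal(cfg$patience, 0L)
  expect_equal(cfg$loss, "mse")
})

test_that("a network fits constant targets and early stopping restores the best epoch", {
  set.seed(10)
  x <- matrix(runif(60 * 32^2), 60)
  y <- matrix(rep(c(0.2, -0.1, 0.3, 0.05), each = 60), 60)
  m <- build_cnn(tiny_arch(), seed = 2)
  cfg <- train_config(max_epochs = 80, patience = 79, seed = 2)
  m <- train_cnn(m, x[1:48, ], y[1:48, ], x[49:60, ], y[49:60, ], cfg)
  pred <- predict(m, x[49:60, ])
  expect_lt(mean(abs(sweep(pred, 2, c(0.2, -0.1, 0.3, 0.05)))), 0.1)
  h <- m$history
  best <- attr(h, "best_epoch")
  expect_lte(best, nrow(h))
  expect_lte(min(h$val_loss), h$val_loss[nrow(h)] + 1e-12)
  expect_equal(m$best_val_loss, min(h$val_loss), tolerance = 1e-7)
  # leakage bookkeeping: fingerprints identify exactly the data slices used
  expect_identical(
    m$data_fingerprint$train, coarseshape:::data_fingerprint(x[1:48, ])
  )
  expect_identical(
    m$data_fingerprint$val, coarseshape:::data_fingerprint(x[49:60, ])
  )
})

test_that("patience 0 stops at the first non-improving epoch", {
  set.seed(11)
  x <- matrix(runif(20 * 32^2), 20)
  y <- matrix(runif(20 * 4), 20)
  m <- build_cnn(tiny_arch(), seed = 3)
  cfg <- train_config(max_epochs = 50, patience = 0, seed = 3)
  m <- train_cnn(m, x, y, x, y, cfg)
  h <- m$history
  n <- nrow(h)
  expect_lte(n, 50)
  if (n < 50) {
    # the run ended exactly when an epoch failed to improve
    expect_gte(h$val_loss[n], min(h$val_loss[1:(n - 1)]))
    expect_equal(attr(h, "best_epoch"), which.min(h$val_loss))
  }
})

test_that("training is deterministic for a fixed seed", {
  set.seed(12)
  x <- matrix(runif(30 * 32^2), 30)
  y <- matrix(runif(30 * 4), 30)
  cfg <- train_config(max_epochs = 5, patience = 4, seed = 7)
  m1 <- train_cnn(build_cnn(tiny_arch(), seed = 7), x[1:24, ], y[1:24, ],
    x[25:30, ], y[25:30, ], cfg
  )
  m2 <- train_cnn(build_cnn(tiny_arch(), seed = 7), x[1:24, ], y[1:24, ],
    x[25:30, ], y[25:30, ], cfg
  )
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
})

test_that("cross-validation partitions samples and never refits scalers on validation", {
  ds <- small_dataset(60, seed = 21)
  cfg <- train_config(max_epochs = 3, patience = 2, seed = 5)
  sc <- cross_validate(tiny_arch(), ds, cfg, folds = 5)
  # every sample in exactly one validation fold
  expect_equal(sort(unique(sc$fold_id)), 1:5)
  expect_equal(length(sc$fold_id), 60)
  expect_equal(nrow(sc$per_fold), 5)
  expect_true(all(sc$per_fold$mae_encoded >= 0))
  # scaler fingerprints equal those of a scaler refit on the train folds only
  for (f in 1:5) {
    tr <- dataset_subset(ds, which(sc$fold_id != f))
    expect_identical(sc$scaler_fingerprints[f], fit_scaler(tr$targets)$fingerprint)
  }
  expect_equal(sc$mean_encoded_mae, mean(sc$per_fold$mae_encoded))

  # identical seeds reproduce folds and scores exactly
  sc2 <- cross_validate(tiny_arch(), ds, cfg, folds = 5)
  expect_identical(sc$fold_id, sc2$fold_id)
  expect_identical(sc$per_fold, sc2$per_fold)
})

test_that("evaluation inverts all transforms and folds orientation modulo pi", {
  ds <- small_dataset(40, seed = 22)
  scaler <- fit_scaler(ds$targets)
  oracle <- function(x) encode_targets(ds$targets, scaler, 4L)
  ev <- evaluate(oracle, ds, scaler)
  expect_equal(ev$mae_L, 0, tolerance = 1e-9)
  expect_equal(ev$mae_l, 0, tolerance = 1e-9)
  expect_equal(ev$mae_alpha, 0, tolerance = 1e-9)

  shifted_pi <- function(x) {
    tg <- ds$targets
    tg$alpha <- tg$alpha + pi
    encode_targets(tg, scaler, 4L)
  }
  expect_equal(evaluate(shifted_pi, ds, scaler)$mae_alpha, 0, tolerance = 1e-9)

  shifted_q <- function(x) {
    tg <- ds$targets
    tg$alpha <- tg$alpha + pi / 4
    encode_targets(tg, scaler, 4L)
  }
  expect_equal(evaluate(shifted_q, ds, scaler)$mae_alpha, pi / 4,
    tolerance = 1e-9
  )
})

test_that("final retraining holds out 10 percent for early stopping only", {
  ds <- small_dataset(60, seed = 23)
  cfg <- train_config(max_epochs = 4, patience = 3, seed = 9)
  fit <- final_retrain(tiny_arch(), ds, cfg)
  expect_s3_class(fit$model, "cnn_model")
  expect_identical(fit$model$scaler_fingerprint, fit$scaler$fingerprint)
  expect_lte(nrow(fit$model$history), 4)
  # the scaler was fitted on the 90% training portion (54 of 60 samples)
  expect_equal(fit$scaler$n, 54)
})

test_that("orientation error grows as tissue anisotropy vanishes (binned report)", {
  ds <- small_dataset(80, seed = 24)
  scaler <- fit_scaler(ds$targets)
  set.seed(4)
  tg_noisy <- ds$targets
  tg_noisy$alpha <- tg_noisy$alpha + rnorm(nrow(tg_noisy), 0, 0.05)
  noisy <- function(x) encode_targets(tg_noisy, scaler, 4L)
  one <- error_vs_anisotropy(noisy, ds, scaler, breaks = 1)
  ev <- evaluate(noisy, ds, scaler)
  expect_equal(one$mae, ev$mae_alpha, tolerance = 1e-9)
  expect_equal(one$count, nrow(ds$targets))

  # explicitly empty bin is reported with count 0 and no crash
  br <- c(0, 1, 50, 100)
  tab <- error_vs_anisotropy(noisy, ds, scaler, breaks = br)
  expect_equal(tab$count[3], 0)
  expect_true(is.nan(tab$mae[3]))
  expect_equal(sum(tab$count), nrow(ds$targets))
})

test_that("training-size ablation errors on oversized requests and matches the pipeline at full size", {
  train_ds <- small_dataset(60, seed = 25)
  test_ds <- small_dataset(30, seed = 26)
  cfg <- train_config(max_epochs = 3, patience = 2, seed = 11)
  expect_error(
    training_size_ablation(tiny_arch(), train_ds, test_ds, sizes = 100, cfg),
    "exceeds"
  )
  ab <- training_size_ablation(tiny_arch(), train_ds, test_ds,
    sizes = 60, cfg, seeds = 11
  )
  # at n = full size, the subset is the whole set: same result as the
  # standard pipeline run with the same seed
  set.seed(11 + 60) # reproduce the (here trivial) subset draw
  idx <- sample(60, 60)
  fit <- final_retrain(tiny_arch(), dataset_subset(train_ds, idx), cfg)
  ev <- evaluate(fit$model, test_ds, fit$scaler)
  expect_equal(ab$mae_L, ev$mae_L, tolerance = 1e-9)
  expect_equal(ab$mae_alpha, ev$mae_alpha, tolerance = 1e-9)
})

test_that("more training data does not hurt at small scale", {
  train_ds <- small_dataset(240, seed = 27)
  test_ds <- small_dataset(60, seed = 28)
  cfg <- train_config(max_epochs = 8, patience = 7, seed = 1)
  ab <- training_size_ablation(tiny_arch(), train_ds, test_ds,
    sizes = c(20, 240), cfg, seeds = 1:3
  )
  med <- tapply(ab$mae_encoded, ab$n, stats::median)
  expect_gte(med[["20"]], med[["240"]])
})

test_that("the periodic mixed loss trains a 3-output model", {
  ds <- small_dataset(40, seed = 29)
  scaler <- fit_scaler(ds$targets)
  x <- normalize_image(ds$tiles, cast = TRUE)
  y <- encode_targets(ds$targets, scaler, 3L)
  cfg <- train_config(max_epochs = 10, patience = 9, loss = "mixed", seed = 2)
  m <- build_cnn(tiny_arch(n_outputs = 3L), seed = 2)
  m <- train_cnn(m, x, y, x[1:10, ], y[1:10, ], cfg)
  expect_true(all(is.finite(m$history$val_loss)))
  expect_lt(m$history$train_loss[10], m$history$train_loss[1])
  # the mixed loss demands 3 outputs
  expect_error(
    train_cnn(build_cnn(tiny_arch(4L)), x, y, x, y, cfg),
    "3-output"
  )
  # training history CSV export
  path <- tempfile(fileext = ".csv")
  write_history_csv(m, path)
  expect_equal(
    names(utils::read.csv(path)), c("epoch", "train_loss", "val_loss")
  )
})
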