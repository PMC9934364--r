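#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 0.001,
#' mean squared error over the encoded targets, early stopping after 20
#' epochs without validation improvement (best weights restored). The batch
#' size is not dictated by the protocol; 32 is the package default.
#'
#' @param learning_rate Adam learning rate.
#' @param max_epochs Epoch budget (200 for full training; the Hyperband search
#'   uses 40).
#' @param patience Early-stopping patience in epochs; must be < `max_epochs`.
#'   `patience = 0` stops at the first non-improving epoch.
#' @param batch_size Minibatch size.
#' @param loss `"mse"` (default, 2 or 4 outputs) or `"mixed"` (3 outputs:
#'   squared axis errors plus the squared orientation error modulo pi).
#' @param seed Integer seed controlling fold assignment, weight
#'   initialization, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, max_epochs = 200L,
                         patience = 20L, batch_size = 32L,
                         loss = c("mse", "mixed"), seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(
    learning_rate > 0, max_epochs >= 1, patience >= 0,
    patience < max_epochs, batch_size >= 1
  )
  structure(
    list(
      learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
      patience = as.integer(patience), batch_size = as.integer(batch_size),
      loss = loss, seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

# normalized inputs + encoded targets for a dataset slice
prepare_xy <- function(ds, scaler, n_outputs, cast = TRUE) {
  list(
    x = normalize_image(ds$tiles, cast = cast),
    y = encode_targets(ds$targets, scaler, n_outputs)
  )
}

# run a cnn_model or a plain prediction function on normalized tiles
model_predictions <- function(model, x) {
  if (is.function(model)) model(x) else predict(model, x)
}

model_n_outputs <- function(model, default = 4L) {
  if (is.function(model)) default else model$arch$n_outputs
}

#' Train a CNN on encoded targets
#'
#' Runs minibatch Adam with early stopping on the validation loss and
#' restores the best-epoch weights. Fingerprints of the training and
#' validation data are recorded on the model so that leakage (e.g. test tiles
#' influencing early stopping) can be asserted later.
#'
#' @param model A `cnn_model` from [build_cnn()].
#' @param x,y Training inputs (one flattened normalized tile per row) and
#'   encoded targets.
#' @param x_val,y_val Validation split used for early stopping.
#' @param config A [train_config()].
#' @return The model with updated weights, `$history` (data frame of epoch,
#'   train and validation loss, with the best epoch as attribute) and data
#'   fingerprints.
#' @export
train_cnn <- function(model, x, y, x_val, y_val, config = train_config()) {
  stopifnot(inherits(model, "cnn_model"), inherits(config, "train_config"))
  loss_type <- if (config$loss == "mixed") 1L else 0L
  if (loss_type == 1L && model$arch$n_outputs != 3L) {
    stop("the mixed periodic loss requires a 3-output architecture")
  }
  res <- cpp_cnn_train(
    model$arch$blocks, model$arch$input_size, model$arch$n_outputs,
    model$arch$dropout_rate, model$weights,
    as.matrix(x), as.matrix(y), as.matrix(x_val), as.matrix(y_val),
    config$max_epochs, config$batch_size, config$learning_rate,
    config$patience, config$seed, loss_type
  )
  model$weights <- res$weights
  model$history <- data.frame(
    epoch = seq_along(res$train_loss),
    train_loss = res$train_loss, val_loss = res$val_loss
  )
  attr(model$history, "best_epoch") <- res$best_epoch
  model$best_val_loss <- res$best_val_loss
  model$data_fingerprint <- list(
    train = data_fingerprint(x), val = data_fingerprint(x_val)
  )
  model
}

#' Write a training history as CSV
#'
#' @param model A trained `cnn_model`.
#' @param path Output CSV path (columns epoch, train_loss, val_loss).
#' @export
write_history_csv <- function(model, path) {
  stopifnot(!is.null(model$history))
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}

#' Per-target evaluation in physical units
#'
#' Axis MAEs are computed in pixels after inverting the scaler; the
#' orientation MAE is computed in radians after decoding the doubled-angle
#' pair, with the angular difference folded modulo pi into `[0, pi/2]`.
#'
#' @param model A trained `cnn_model`, or a function mapping the normalized
#'   tile matrix to an encoded prediction matrix (an "oracle model").
#' @param ds A `tile_dataset` to evaluate on.
#' @param scaler The `axis_scaler` used at training time.
#' @param n_outputs Output count when `model` is a plain function (default 4).
#' @return A list: `mae_L`, `mae_l` (pixels), `mae_alpha` (radians, `NA` for
#'   axes-only models), `mae_encoded` (per encoded target and their mean) and
#'   `n`.
#' @export
evaluate <- function(model, ds, scaler, n_outputs = 4L) {
  stopifnot(inherits(ds, "tile_dataset"))
  xy <- prepare_xy(ds, scaler, model_n_outputs(model, n_outputs))
  pred <- model_predictions(model, xy$x)
  enc_mae <- colMeans(abs(pred - xy$y))
  dec <- decode_predictions(pred, scaler)
  out <- list(
    mae_L = mean(abs(dec$L - ds$targets$L)),
    mae_l = mean(abs(dec$l - ds$targets$l)),
    mae_alpha = NA_real_,
    mae_encoded = c(enc_mae, mean = mean(enc_mae)),
    n = nrow(ds$targets)
  )
  if (!is.null(dec$alpha)) {
    out$mae_alpha <- mean(abs(fold_angle_diff(dec$alpha - ds$targets$alpha)))
  }
  out
}

#' Five-fold cross-validation of one architecture
#'
#' The dataset is split into `folds` disjoint seeded folds; one fresh model
#' is trained per fold (scaler refitted on that fold's training portion only)
#' and scored on the held-out fold. The selection criterion is the validation
#' MAE averaged over folds and over the encoded targets.
#'
#' @param arch An [arch_spec()].
#' @param ds A `tile_dataset`.
#' @param config A [train_config()].
#' @param folds Number of folds (default 5).
#' @return An object of class `model_score`: per-fold data frame of MAEs
#'   (encoded space and physical units), their means, the selection value
#'   `mean_encoded_mae`, fold assignment and per-fold scaler fingerprints.
#' @export
cross_validate <- function(arch, ds, config = train_config(), folds = 5L) {
  stopifnot(inherits(arch, "arch_spec"), inherits(ds, "tile_dataset"))
  n <- nrow(ds$tiles)
  if (n < 2 * folds) stop("dataset too small for ", folds, "-fold CV")
  set.seed(config$seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  per_fold <- vector("list", folds)
  scaler_fps <- character(folds)
  for (f in seq_len(folds)) {
    tr <- dataset_subset(ds, which(fold_id != f))
    va <- dataset_subset(ds, which(fold_id == f))
    scaler <- fit_scaler(tr$targets)
    scaler_fps[f] <- scaler$fingerprint
    xy_tr <- prepare_xy(tr, scaler, arch$n_outputs)
    xy_va <- prepare_xy(va, scaler, arch$n_outputs)
    cfg <- config
    cfg$seed <- config$seed + f
    model <- build_cnn(arch, seed = cfg$seed)
    model <- train_cnn(model, xy_tr$x, xy_tr$y, xy_va$x, xy_va$y, cfg)
    ev <- evaluate(model, va, scaler)
    per_fold[[f]] <- data.frame(
      fold = f,
      mae_encoded = ev$mae_encoded[["mean"]],
      mae_L = ev$mae_L, mae_l = ev$mae_l, mae_alpha = ev$mae_alpha,
      val_mse = model$best_val_loss
    )
  }
  tab <- do.call(rbind, per_fold)
  structure(
    list(
      per_fold = tab,
      mean_encoded_mae = mean(tab$mae_encoded),
      mean_mse = mean(tab$val_mse),
      means = colMeans(tab[, -1, drop = FALSE]),
      fold_id = fold_id,
      scaler_fingerprints = scaler_fps,
      arch_key = arch_key(arch)
    ),
    class = "model_score"
  )
}

#' @export
print.model_score <- function(x, ...) {
  cat(sprintf(
    "CV score for %s: encoded MAE %.4f (L %.2f px, l %.2f px, alpha %s rad)\n",
    x$arch_key, x$mean_encoded_mae, x$means[["mae_L"]], x$means[["mae_l"]],
    ifelse(is.na(x$means[["mae_alpha"]]), "-",
      sprintf("%.3f", x$means[["mae_alpha"]])
    )
  ))
  invisible(x)
}

#' Final retraining on the full training set
#'
#' After model selection, the chosen architecture is retrained once from
#' scratch on the whole training set, keeping a seeded random `val_fraction`
#' (10% by default) as validation for early stopping; best-epoch weights are
#' restored. The scaler is fitted on the training portion.
#'
#' @param arch An [arch_spec()].
#' @param ds Training `tile_dataset`.
#' @param config A [train_config()].
#' @param val_fraction Held-out fraction used only for early stopping.
#' @return A list with the trained `model` and its `scaler`.
#' @export
final_retrain <- function(arch, ds, config = train_config(),
                          val_fraction = 0.1) {
  n <- nrow(ds$tiles)
  set.seed(config$seed)
  n_val <- max(1L, round(val_fraction * n))
  val_idx <- sample(n, n_val)
  tr <- dataset_subset(ds, setdiff(seq_len(n), val_idx))
  va <- dataset_subset(ds, val_idx)
  scaler <- fit_scaler(tr$targets)
  xy_tr <- prepare_xy(tr, scaler, arch$n_outputs)
  xy_va <- prepare_xy(va, scaler, arch$n_outputs)
  model <- build_cnn(arch, seed = config$seed)
  model <- train_cnn(model, xy_tr$x, xy_tr$y, xy_va$x, xy_va$y, config)
  model$scaler_fingerprint <- scaler$fingerprint
  list(model = model, scaler = scaler)
}

#' Orientation error as a function of ground-truth anisotropy
#'
#' Orientation is the angle of the window-averaged ellipse; as the average
#' cell becomes round (anisotropy near 0) the quantity itself is ill-defined
#' and the error necessarily grows. This bins the absolute orientation errors
#' by the ground-truth anisotropy of each tile.
#'
#' @param model Trained 4-output `cnn_model` (or an oracle prediction
#'   function, as in [evaluate()]).
#' @param ds Evaluation `tile_dataset`.
#' @param scaler The training `axis_scaler`.
#' @param breaks Either a number of equal-width bins or a vector of bin edges.
#' @return Data frame with `bin_lo`, `bin_hi`, `bin_center`, `mae`
#'   (radians; `NaN` for empty bins) and `count`.
#' @export
error_vs_anisotropy <- function(model, ds, scaler, breaks = 6) {
  stopifnot(model_n_outputs(model) == 4L)
  xy <- prepare_xy(ds, scaler, 4L)
  pred <- model_predictions(model, xy$x)
  dec <- decode_predictions(pred, scaler)
  err <- abs(fold_angle_diff(dec$alpha - ds$targets$alpha))
  a <- ds$targets$anisotropy
  if (length(breaks) == 1) {
    breaks <- seq(min(a), max(a), length.out = breaks + 1)
  }
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  bin <- findInterval(a, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  data.frame(
    bin_lo = lo, bin_hi = hi, bin_center = (lo + hi) / 2,
    mae = vapply(seq_along(lo), function(b) mean(err[bin == b]), numeric(1)),
    count = vapply(seq_along(lo), function(b) sum(bin == b), integer(1))
  )
}

#' Performance as a function of training-set size
#'
#' For each requested size, a seeded random subset of the training set is
#' drawn, a fresh model is trained on it (via [final_retrain()]) and
#' evaluated on the fixed test set.
#'
#' @param arch An [arch_spec()].
#' @param train_ds,test_ds Training and fixed test `tile_dataset`s.
#' @param sizes Vector of training-set sizes (each <= size of `train_ds`).
#' @param config A [train_config()].
#' @param seeds One or more seeds; each (size, seed) pair trains one model.
#' @return Data frame with one row per (size, seed): `n`, `seed`, `mae_L`,
#'   `mae_l`, `mae_alpha`, `mae_encoded`.
#' @export
training_size_ablation <- function(arch, train_ds, test_ds, sizes,
                                   config = train_config(),
                                   seeds = config$seed) {
  n_avail <- nrow(train_ds$tiles)
  if (any(sizes > n_avail)) {
    stop("requested subset size exceeds the training set (", n_avail, ")")
  }
  rows <- list()
  for (s in seeds) {
    for (n in sizes) {
      cfg <- config
      cfg$seed <- as.integer(s)
      set.seed(cfg$seed + n)
      sub <- dataset_subset(train_ds, sample(n_avail, n))
      fit <- final_retrain(arch, sub, cfg)
      ev <- evaluate(fit$model, test_ds, fit$scaler)
      rows[[length(rows) + 1]] <- data.frame(
        n = n, seed = s, mae_L = ev$mae_L, mae_l = ev$mae_l,
        mae_alpha = ev$mae_alpha, mae_encoded = ev$mae_encoded[["mean"]]
      )
    }
  }
  do.call(rbind, rows)
}
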