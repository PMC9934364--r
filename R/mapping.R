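#' Coarse-grained shape map of a large tissue image
#'
#' Tiles the image into overlapping windows, runs the model on every
#' normalized window, inverts the axis scaler (and decodes the orientation
#' when the model predicts it), and assembles one map pixel per window in
#' row-major window order. Clamped trailing windows keep their own map pixel,
#' matching the one-measurement-per-window semantics.
#'
#' @param image Numeric matrix of 8-bit gray values (0..255).
#' @param model A trained `cnn_model`, or a function
#'   `function(x) -> prediction matrix` taking the normalized window matrix
#'   (one flattened window per row) — useful for oracle models in tests.
#' @param scaler The `axis_scaler` of the model. When the model carries a
#'   scaler fingerprint (from [final_retrain()]), a mismatch is an error.
#' @param tile Window side in pixels; must equal the model input size.
#' @param overlap Window overlap fraction (default 0.25).
#' @return An object of class `shape_map`: matrices `L`, `l`, `alpha`,
#'   `anisotropy` (map_rows x map_cols), the window origin grids, and
#'   provenance (tile, overlap, scaler fingerprint).
#' @export
predict_map <- function(image, model, scaler, tile = 128L, overlap = 0.25) {
  stopifnot(is.matrix(image))
  if (inherits(model, "cnn_model")) {
    if (model$arch$input_size != tile) {
      stop(
        "model input size ", model$arch$input_size,
        " does not match tile ", tile
      )
    }
    if (!is.null(model$scaler_fingerprint) &&
      !identical(model$scaler_fingerprint, scaler$fingerprint)) {
      stop("scaler fingerprint does not match the one used at training time")
    }
    predict_fun <- function(x) predict(model, x)
  } else {
    stopifnot(is.function(model))
    predict_fun <- model
  }
  wins <- tile_image(dim(image), tile, overlap)
  x <- matrix(0, nrow(wins), tile^2)
  for (i in seq_len(nrow(wins))) {
    x[i, ] <- as.numeric(
      image[wins$row[i] + seq_len(tile), wins$col[i] + seq_len(tile)]
    )
  }
  pred <- predict_fun(normalize_image(x, cast = TRUE))
  dec <- decode_predictions(pred, scaler)

  ro <- unique(wins$row)
  co <- unique(wins$col)
  shape <- c(length(ro), length(co))
  to_grid <- function(v) matrix(v, shape[1], shape[2], byrow = TRUE)
  L <- to_grid(dec$L)
  l <- to_grid(dec$l)
  alpha <- if (is.null(dec$alpha)) {
    matrix(NA_real_, shape[1], shape[2])
  } else {
    to_grid(dec$alpha)
  }
  structure(
    list(
      L = L, l = l, alpha = alpha, anisotropy = L / l - 1,
      row_origins = ro, col_origins = co, tile = as.integer(tile),
      overlap = overlap, scaler_fingerprint = scaler$fingerprint
    ),
    class = "shape_map"
  )
}

#' @export
print.shape_map <- function(x, ...) {
  cat(sprintf(
    "shape map %d x %d windows (tile %d, overlap %.0f%%); anisotropy %.2f-%.2f\n",
    nrow(x$L), ncol(x$L), x$tile, 100 * x$overlap,
    min(x$anisotropy), max(x$anisotropy)
  ))
  invisible(x)
}

#' @export
as.data.frame.shape_map <- function(x, ...) {
  grid <- expand.grid(
    col = x$col_origins, row = x$row_origins,
    KEEP.OUT.ATTRS = FALSE
  )
  data.frame(
    row = grid$row, col = grid$col,
    L = as.vector(t(x$L)), l = as.vector(t(x$l)),
    alpha = as.vector(t(x$alpha)), anisotropy = as.vector(t(x$anisotropy))
  )
}

#' Write a shape map as CSV (one row per window)
#'
#' @param map A `shape_map`.
#' @param path Output CSV path.
#' @export
write_map_csv <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

#' Render a map channel as a grayscale PNG heatmap (visualization only)
#'
#' Map pixels are upsampled with nearest-neighbour repetition; values are
#' linearly rescaled to the gray range.
#'
#' @param map A `shape_map`.
#' @param path Output PNG path.
#' @param what Channel to render.
#' @param scale_px Pixels per map cell.
#' @export
write_map_png <- function(map, path, what = c("anisotropy", "L", "l", "alpha"),
                          scale_px = 8L) {
  what <- match.arg(what)
  m <- map[[what]]
  rng <- range(m, finite = TRUE)
  norm <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  big <- norm[rep(seq_len(nrow(m)), each = scale_px),
    rep(seq_len(ncol(m)), each = scale_px),
    drop = FALSE
  ]
  png::writePNG(big, path)
  invisible(path)
}

#' Axes-only training and anisotropy mapping on one large tissue
#'
#' Demonstration workflow for anisotropy mapping of a single large image with
#' a spatially disjoint train/test split: the image (and its labels) is cut
#' in half by rows; 128x128 windows with 25% overlap are extracted within
#' each half (no window crosses the split line). A compact 3-layer axes-only
#' CNN (by default 64 filters of size 5 in every layer, 2 outputs, dropout
#' 0.2 after each convolution) is trained on the top-half windows, keeping
#' 20% of them as validation for early stopping, and the trained model then
#' predicts the bottom-half anisotropy map.
#'
#' @param image Numeric gray matrix (0..255).
#' @param labels Matching integer label image (ground-truth source).
#' @param arch Architecture of the axes-only model.
#' @param config A [train_config()].
#' @param tile,overlap Window geometry.
#' @param val_fraction Fraction of training windows kept for early stopping.
#' @return A list: `map` (predicted bottom-half `shape_map`), `truth_map`
#'   (ground-truth anisotropy grid of the bottom half), `model`, `scaler`,
#'   `train_targets`, `test_targets`, and the split row.
#' @export
chicken_workflow <- function(image, labels,
                             arch = arch_spec(
                               list(c(64, 5), c(64, 5), c(64, 5)),
                               n_outputs = 2L
                             ),
                             config = train_config(),
                             tile = 128L, overlap = 0.25,
                             val_fraction = 0.2) {
  stopifnot(all(dim(image) == dim(labels)), arch$n_outputs == 2L)
  H <- nrow(image)
  split_row <- H %/% 2
  top_rows <- seq_len(split_row)
  bot_rows <- (split_row + 1):H

  train_targets <- window_targets(labels[top_rows, , drop = FALSE],
    tile = tile, overlap = overlap
  )
  test_targets <- window_targets(labels[bot_rows, , drop = FALSE],
    tile = tile, overlap = overlap
  )

  wins <- tile_image(c(length(top_rows), ncol(image)), tile, overlap)
  xs <- matrix(0, nrow(wins), tile^2)
  top_img <- image[top_rows, , drop = FALSE]
  for (i in seq_len(nrow(wins))) {
    xs[i, ] <- as.numeric(
      top_img[wins$row[i] + seq_len(tile), wins$col[i] + seq_len(tile)]
    )
  }
  ds <- structure(
    list(tiles = xs, targets = train_targets, tile_size = as.integer(tile),
         seed = config$seed),
    class = "tile_dataset"
  )
  fit <- final_retrain(arch, ds, config, val_fraction = val_fraction)

  map <- predict_map(image[bot_rows, , drop = FALSE], fit$model, fit$scaler,
    tile = tile, overlap = overlap
  )
  truth <- matrix(test_targets$anisotropy,
    nrow = length(unique(test_targets$row)), byrow = TRUE
  )
  list(
    map = map, truth_map = truth, model = fit$model, scaler = fit$scaler,
    train_targets = train_targets, test_targets = test_targets,
    split_row = split_row
  )
}
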