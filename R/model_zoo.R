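#' Architecture specification of a compact shape-regression CNN
#'
#' The family consists of N repeated blocks of (same-padded stride-1
#' convolution + ReLU, 2x2 max pooling, dropout 0.2), followed by a flatten
#' and a linear dense layer with one neuron per target. The tunable part is
#' the ordered list of `(n_filters, kernel_size)` per block.
#'
#' @param blocks A list of `c(n_filters, kernel_size)` pairs, or an N x 2
#'   integer matrix (one row per block). Kernel sizes must be odd and >= 3.
#' @param n_outputs Number of regression outputs: 4 by default (scaled long
#'   and short axes plus cos/sin of the doubled orientation), 2 for an
#'   axes-only model, 3 for the raw-angle periodic-loss variant.
#' @param input_size Input tile side in pixels (default 128); must remain a
#'   whole number after halving once per block.
#' @param dropout_rate Dropout fraction after every pooling (default 0.2).
#' @return An object of class `arch_spec`.
#' @export
#' @examples
#' arch_spec(list(c(8, 5), c(64, 9), c(128, 3)))
arch_spec <- function(blocks, n_outputs = 4L, input_size = 128L,
                      dropout_rate = 0.2) {
  if (is.list(blocks)) blocks <- do.call(rbind, blocks)
  blocks <- matrix(as.integer(blocks), ncol = 2)
  n <- nrow(blocks)
  stopifnot(
    n >= 1, all(blocks[, 1] >= 1),
    all(blocks[, 2] >= 3), all(blocks[, 2] %% 2 == 1),
    n_outputs %in% 2:4, dropout_rate >= 0, dropout_rate < 1
  )
  if (input_size %% 2^n != 0) {
    stop(
      "input_size ", input_size, " is not divisible by 2^", n,
      " (one 2x2 pooling per block)"
    )
  }
  colnames(blocks) <- c("n_filters", "kernel_size")
  structure(
    list(
      blocks = blocks, n_outputs = as.integer(n_outputs),
      input_size = as.integer(input_size), dropout_rate = dropout_rate,
      pool_size = 2L
    ),
    class = "arch_spec"
  )
}

#' @export
print.arch_spec <- function(x, ...) {
  cat(
    "CNN architecture:",
    paste(sprintf("%d@%d", x$blocks[, 1], x$blocks[, 2]), collapse = " -> "),
    sprintf(
      "-> dense(%d), input %dx%d\n",
      x$n_outputs, x$input_size, x$input_size
    )
  )
  invisible(x)
}

# short deterministic identity string, used as table key and for tie-breaking
arch_key <- function(arch) {
  paste0(
    paste(sprintf("%d@%d", arch$blocks[, 1], arch$blocks[, 2]),
      collapse = "-"
    ),
    "-o", arch$n_outputs, "-i", arch$input_size
  )
}

#' Analytic parameter count of an architecture
#'
#' Block `i` contributes `n_i * (k_i^2 * c_(i-1) + 1)` weights (with `c_0 =
#' 1`), the flatten has `(input / 2^N)^2 * n_N` units, and the dense head adds
#' `flatten * n_outputs + n_outputs`. Every parameter is trainable. The count
#' is exact: it always equals the number of weights of the built model.
#'
#' @param arch An [arch_spec()].
#' @return A list of class `param_count` with `trainable`, `total` and a
#'   per-layer breakdown.
#' @export
#' @examples
#' count_params(arch_spec(list(c(64, 3))))$trainable # 1,049,220
count_params <- function(arch) {
  stopifnot(inherits(arch, "arch_spec"))
  c_prev <- 1
  by_layer <- numeric(0)
  for (i in seq_len(nrow(arch$blocks))) {
    n <- arch$blocks[i, 1]
    k <- arch$blocks[i, 2]
    by_layer <- c(by_layer, n * (k^2 * c_prev + 1))
    c_prev <- n
  }
  side <- arch$input_size / 2^nrow(arch$blocks)
  flat <- side^2 * c_prev
  by_layer <- c(by_layer, flat * arch$n_outputs + arch$n_outputs)
  names(by_layer) <- c(
    paste0("conv", seq_len(nrow(arch$blocks))), "dense"
  )
  structure(
    list(trainable = sum(by_layer), total = sum(by_layer),
         by_layer = by_layer),
    class = "param_count"
  )
}

#' @export
print.param_count <- function(x, ...) {
  cat(sprintf(
    "parameters: %s trainable, %s total\n",
    format(x$trainable, big.mark = ","), format(x$total, big.mark = ",")
  ))
  invisible(x)
}

#' Build a trainable CNN from an architecture specification
#'
#' Weights are Glorot-uniform initialized from a dedicated seeded generator;
#' biases start at zero. The engine-reported weight count (`n_params`) always
#' equals [count_params()].
#'
#' @param arch An [arch_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `cnn_model` holding the architecture and a
#'   named list of flat weight vectors.
#' @export
build_cnn <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "arch_spec"))
  w <- cpp_cnn_init(
    arch$blocks, arch$input_size, arch$n_outputs, arch$dropout_rate,
    as.integer(seed)
  )
  structure(
    list(
      arch = arch, weights = w, n_params = sum(lengths(w)),
      init_seed = as.integer(seed), history = NULL,
      scaler_fingerprint = NULL, data_fingerprint = NULL
    ),
    class = "cnn_model"
  )
}

#' @export
print.cnn_model <- function(x, ...) {
  print(x$arch)
  cat(sprintf(
    "  %s parameters%s\n", format(x$n_params, big.mark = ","),
    if (is.null(x$history)) " (untrained)" else {
      sprintf(", trained %d epochs (best %d)",
              nrow(x$history), attr(x$history, "best_epoch"))
    }
  ))
  invisible(x)
}

#' Predict encoded targets for a batch of normalized tiles
#'
#' @param object A `cnn_model`.
#' @param x A numeric matrix with one flattened tile per row (values in
#'   `[0, 1]`), or a single `input_size` x `input_size` matrix.
#' @param ... Unused.
#' @return Matrix of raw (encoded-space) predictions, one row per tile.
#' @export
predict.cnn_model <- function(object, x, ...) {
  if (is.matrix(x) && nrow(x) == object$arch$input_size &&
    ncol(x) == object$arch$input_size) {
    x <- matrix(as.numeric(x), nrow = 1)
  }
  stopifnot(ncol(x) == object$arch$input_size^2)
  cpp_cnn_predict(
    object$arch$blocks, object$arch$input_size, object$arch$n_outputs,
    object$arch$dropout_rate, object$weights, x
  )
}

#' Topology of the frozen-base transfer architecture
#'
#' The reference transfer setup reuses the 16-convolution / 5-pool base of a
#' large ImageNet classifier (channel structure 2x64, 2x128, 4x256, 4x512,
#' 4x512, all 3x3 kernels, 128x128x3 input), freezes it, and adds a trainable
#' head: dense(128, ReLU) then dense(n_outputs, linear). Only the topology
#' and its parameter accounting are represented; no pre-trained weights are
#' involved.
#'
#' @param n_outputs Outputs of the regression head (default 4).
#' @return An object of class `transfer_arch`.
#' @export
transfer_arch <- function(n_outputs = 4L) {
  structure(
    list(
      base_channels = c(64, 64, 128, 128, 256, 256, 256, 256,
                        512, 512, 512, 512, 512, 512, 512, 512),
      pool_after = c(2, 4, 8, 12, 16), # 5 poolings
      kernel = 3L, input = c(128L, 128L, 3L),
      head = c(128L, as.integer(n_outputs))
    ),
    class = "transfer_arch"
  )
}

#' Parameter accounting for the transfer architecture
#'
#' The frozen convolutional base is counted from its topology; the trainable
#' head is `flatten * 128 + 128` plus `128 * n_outputs + n_outputs` with
#' `flatten = (128 / 2^5)^2 * 512 = 8192`.
#'
#' @param spec A [transfer_arch()].
#' @return A `param_count` with `trainable` (head only) and `total`
#'   (base + head).
#' @export
#' @examples
#' count_transfer_params()$total # 21,073,604
count_transfer_params <- function(spec = transfer_arch()) {
  stopifnot(inherits(spec, "transfer_arch"))
  c_prev <- spec$input[3]
  base <- 0
  for (n in spec$base_channels) {
    base <- base + n * (spec$kernel^2 * c_prev + 1)
    c_prev <- n
  }
  side <- spec$input[1] / 2^length(spec$pool_after)
  flat <- side^2 * c_prev
  head <- flat * spec$head[1] + spec$head[1] +
    spec$head[1] * spec$head[2] + spec$head[2]
  structure(
    list(trainable = head, total = base + head,
         by_layer = c(base = base, head = head)),
    class = "param_count"
  )
}

#' Serialize / restore an architecture as JSON
#'
#' @param arch An [arch_spec()].
#' @param path File path; when `NULL`, the JSON string is returned.
#' @return `arch_to_json`: the JSON string (invisibly when written to file);
#'   `arch_from_json`: an `arch_spec`.
#' @export
arch_to_json <- function(arch, path = NULL) {
  stopifnot(inherits(arch, "arch_spec"))
  js <- jsonlite::toJSON(
    list(
      blocks = lapply(
        seq_len(nrow(arch$blocks)),
        function(i) unname(arch$blocks[i, ])
      ),
      n_outputs = arch$n_outputs, input_size = arch$input_size,
      dropout_rate = arch$dropout_rate
    ),
    auto_unbox = TRUE
  )
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' @rdname arch_to_json
#' @param json JSON string or file path (for `arch_from_json`).
#' @export
arch_from_json <- function(json) {
  if (file.exists(json)) json <- paste(readLines(json), collapse = "")
  p <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  blocks <- if (is.matrix(p$blocks)) p$blocks else do.call(rbind, p$blocks)
  arch_spec(
    blocks = blocks,
    n_outputs = p$n_outputs, input_size = p$input_size,
    dropout_rate = p$dropout_rate
  )
}

#' Save / load a trained model (weights + architecture + scaler side files)
#'
#' Writes `<prefix>_arch.json`, `<prefix>_weights.rds` and, when a scaler is
#' supplied, `<prefix>_scaler.json`, so predictions can later be inverted to
#' pixel units.
#'
#' @param model A `cnn_model`.
#' @param prefix Path prefix for the three files.
#' @param scaler Optional `axis_scaler` to store alongside.
#' @return `save_cnn`: the prefix, invisibly. `load_cnn`: a list with
#'   `model` and `scaler` (`NULL` when absent).
#' @export
save_cnn <- function(model, prefix, scaler = NULL) {
  stopifnot(inherits(model, "cnn_model"))
  arch_to_json(model$arch, paste0(prefix, "_arch.json"))
  saveRDS(model, paste0(prefix, "_weights.rds"))
  if (!is.null(scaler)) {
    writeLines(
      as.character(jsonlite::toJSON(unclass(scaler), auto_unbox = TRUE)),
      paste0(prefix, "_scaler.json")
    )
  }
  invisible(prefix)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(prefix) {
  model <- readRDS(paste0(prefix, "_weights.rds"))
  scaler <- NULL
  sp <- paste0(prefix, "_scaler.json")
  if (file.exists(sp)) {
    scaler <- structure(
      jsonlite::fromJSON(paste(readLines(sp), collapse = "")),
      class = "axis_scaler"
    )
  }
  list(model = model, scaler = scaler)
}
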