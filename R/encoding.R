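#' Encode an orientation as the cosine and sine of the doubled angle
#'
#' Cell orientation is defined modulo pi, so a raw-angle regression target has
#' a wrap-around discontinuity: 0 and pi are the same physical orientation but
#' maximally distant numbers. Doubling the angle maps the half-circle of
#' orientations onto the full circle, and the (cos 2a, sin 2a) pair is then a
#' continuous, bounded representation that an ordinary MSE loss handles well.
#'
#' @param alpha Orientation(s) in radians; reduced modulo pi before encoding.
#' @return A numeric matrix with columns `cos2a` and `sin2a`, one row per
#'   input angle. The pair always lies exactly on the unit circle.
#' @seealso [decode_orientation()] for the inverse transform.
#' @export
#' @examples
#' encode_orientation(c(0, pi / 4, pi / 2))
encode_orientation <- function(alpha) {
  stopifnot(is.numeric(alpha), all(is.finite(alpha)))
  a <- alpha %% pi
  cbind(cos2a = cos(2 * a), sin2a = sin(2 * a))
}

#' Decode a (cos 2a, sin 2a) pair back to an orientation in [0, pi)
#'
#' Uses the two-argument arctangent divided by two. The decoding is invariant
#' under positive rescaling of the pair, so model predictions need not lie on
#' the unit circle.
#'
#' @param c,s Cosine and sine components (vectors of equal length).
#' @return Orientation(s) in radians in `[0, pi)`.
#' @export
decode_orientation <- function(c, s) {
  stopifnot(length(c) == length(s), all(is.finite(c)), all(is.finite(s)))
  if (any(c == 0 & s == 0)) {
    stop("orientation is undefined for (cos, sin) = (0, 0)")
  }
  (atan2(s, c) / 2) %% pi
}

#' Fit a standard scaler to the long and short axis targets
#'
#' Centres and scales the axis targets; the encoded angle components are
#' already bounded in \[-1, 1\] and are deliberately left untouched. The
#' scaler must be fitted on training targets only; it carries a fingerprint of
#' the data it was fitted on so that leakage can be asserted downstream.
#'
#' @param targets A data frame with numeric columns `L` and `l` (pixels).
#' @return An object of class `axis_scaler` with per-axis mean and sd.
#' @export
fit_scaler <- function(targets) {
  stopifnot(is.data.frame(targets), all(c("L", "l") %in% names(targets)))
  if (nrow(targets) < 2) stop("need at least 2 training samples to fit a scaler")
  sds <- c(stats::sd(targets$L), stats::sd(targets$l))
  if (any(sds <= 0) || any(!is.finite(sds))) {
    stop("zero-variance axis targets; cannot fit scaler")
  }
  structure(
    list(
      mean_L = mean(targets$L), sd_L = sds[1],
      mean_l = mean(targets$l), sd_l = sds[2],
      n = nrow(targets),
      fingerprint = data_fingerprint(targets[, c("L", "l")])
    ),
    class = "axis_scaler"
  )
}

#' @export
print.axis_scaler <- function(x, ...) {
  cat(sprintf(
    "axis scaler (n = %d): L ~ %.2f +- %.2f px, l ~ %.2f +- %.2f px\n",
    x$n, x$mean_L, x$sd_L, x$mean_l, x$sd_l
  ))
  invisible(x)
}

#' Apply / invert an axis scaler
#'
#' @param scaler An `axis_scaler` from [fit_scaler()].
#' @param targets Data frame with `L`, `l` columns (for `scaler_apply`).
#' @param z Matrix with standardized columns `zL`, `zl` (for `scaler_invert`).
#' @return `scaler_apply`: matrix with columns `zL`, `zl`;
#'   `scaler_invert`: matrix with columns `L`, `l` in pixels.
#' @export
scaler_apply <- function(scaler, targets) {
  stopifnot(inherits(scaler, "axis_scaler"))
  cbind(
    zL = (targets$L - scaler$mean_L) / scaler$sd_L,
    zl = (targets$l - scaler$mean_l) / scaler$sd_l
  )
}

#' @rdname scaler_apply
#' @export
scaler_invert <- function(scaler, z) {
  stopifnot(inherits(scaler, "axis_scaler"), ncol(z) >= 2)
  cbind(
    L = z[, 1] * scaler$sd_L + scaler$mean_L,
    l = z[, 2] * scaler$sd_l + scaler$mean_l
  )
}

#' Build the full encoded target matrix a network is fitted to
#'
#' @param targets Data frame with `L`, `l` (pixels) and `alpha` (radians).
#' @param scaler An `axis_scaler` fitted on the training targets.
#' @param n_outputs 4 (axes + doubled-angle pair), 3 (axes + raw angle, for
#'   the periodic-loss training strategy) or 2 (axes only).
#' @return Numeric matrix with `n_outputs` columns.
#' @export
encode_targets <- function(targets, scaler, n_outputs = 4L) {
  z <- scaler_apply(scaler, targets)
  if (n_outputs == 2L) return(z)
  if (n_outputs == 3L) return(cbind(z, alpha = targets$alpha %% pi))
  if (n_outputs == 4L) return(cbind(z, encode_orientation(targets$alpha)))
  stop("n_outputs must be 2, 3 or 4")
}

#' Invert model predictions back to physical units
#'
#' @param pred Prediction matrix from a model (2, 3 or 4 columns).
#' @param scaler The `axis_scaler` used at training time.
#' @return Data frame with `L`, `l` in pixels and, when the model predicts
#'   orientation, `alpha` in radians in `[0, pi)`.
#' @export
decode_predictions <- function(pred, scaler) {
  ax <- scaler_invert(scaler, pred)
  out <- data.frame(L = ax[, 1], l = ax[, 2])
  if (ncol(pred) == 3L) out$alpha <- pred[, 3] %% pi
  if (ncol(pred) == 4L) out$alpha <- decode_orientation(pred[, 3], pred[, 4])
  out
}

#' Normalize an 8-bit grayscale tile to [0, 1]
#'
#' Divides by 255, the fixed 8-bit maximum. Per-image maximum rescaling is
#' deliberately not offered: it would give each tile its own intensity scale
#' and introduce artefacts between tiles.
#'
#' @param tile Numeric matrix (or vector) of 8-bit gray values in 0..255.
#' @param cast If `TRUE`, non-integer values in \[0, 255\] are accepted and
#'   divided by 255 anyway; otherwise they are an error.
#' @return The input divided by 255.
#' @export
normalize_image <- function(tile, cast = FALSE) {
  stopifnot(is.numeric(tile))
  if (any(!is.finite(tile)) || any(tile < 0) || any(tile > 255)) {
    stop("tile values must be finite and within [0, 255]")
  }
  if (!cast && any(abs(tile - round(tile)) > 1e-8)) {
    stop("tile is not 8-bit integer data; pass cast = TRUE to accept it")
  }
  tile / 255
}

#' Squared orientation error modulo pi
#'
#' The angular difference is folded into \[-pi/2, pi/2\] before squaring, so
#' that e.g. predictions of 0.01 and pi - 0.01 count as a 0.02 rad error.
#' This is the per-sample orientation term of the alternative "mixed" training
#' strategy that regresses the raw angle with a periodic loss.
#'
#' @param alpha_pred,alpha_true Orientations in radians (vectors recycle).
#' @return Squared folded difference(s), bounded by `(pi / 2)^2`.
#' @export
circular_squared_error <- function(alpha_pred, alpha_true) {
  fold_angle_diff(alpha_pred - alpha_true)^2
}

# fold an angular difference into [-pi/2, pi/2)
fold_angle_diff <- function(d) {
  ((d + pi / 2) %% pi) - pi / 2
}

# order-insensitive-ish identity token for a chunk of numeric data; used to
# assert that scalers and models were fitted on exactly the data they claim
data_fingerprint <- function(x) {
  v <- as.numeric(unlist(x, use.names = FALSE))
  sprintf("n%d|s%.10e|q%.10e", length(v), sum(v), sum(v * v))
}
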