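#' Second central moments of one cell in a label image
#'
#' The inertia tensor of a cell is the 2x2 matrix of second central moments of
#' its pixel coordinates: `M = mean over pixels of (p - centroid)(p - centroid)'`
#' with `p = (x, y)`, `x` the 0-based column and `y` the 0-based row index.
#' Its eigen-structure defines the cell's equivalent ellipse.
#'
#' @param labels Integer matrix; 0 marks boundary/background, positive values
#'   are cell IDs.
#' @param cell_id A positive integer present in `labels`.
#' @return A list of class `cell_moments`: `area` (pixel count), `centroid`
#'   (`c(x, y)` in pixels) and `M` (symmetric 2x2 matrix, pixels^2).
#' @export
cell_moments <- function(labels, cell_id) {
  stopifnot(is.numeric(cell_id), length(cell_id) == 1, cell_id > 0)
  idx <- which(labels == cell_id)
  if (length(idx) == 0) stop("cell ID ", cell_id, " not present in labels")
  rc <- arrayInd(idx, dim(labels))
  x <- rc[, 2] - 1
  y <- rc[, 1] - 1
  mx <- mean(x)
  my <- mean(y)
  M <- matrix(c(
    mean((x - mx)^2), mean((x - mx) * (y - my)),
    mean((x - mx) * (y - my)), mean((y - my)^2)
  ), 2, 2)
  structure(list(area = length(idx), centroid = c(x = mx, y = my), M = M),
    class = "cell_moments"
  )
}

#' Window-averaged cell shape from a label image
#'
#' Computes the coarse-grained shape targets of one window: per-cell
#' normalized moment matrices are averaged over the cells of the window and
#' the averaged matrix is eigendecomposed. With eigenvalues `l1 >= l2` and
#' principal direction `theta`, the full equivalent-ellipse axes are
#' `L = 4 sqrt(l1)` and `l = 4 sqrt(l2)` (a uniform ellipse with semi-axis `a`
#' has second moment `a^2 / 4`), and the orientation is `theta mod pi`,
#' measured from the +x (column) axis towards +y (row).
#'
#' Cells are clipped to the window; a cell enters the average only if at least
#' `min_inside` of its pixels (counted over the full label image) fall inside.
#' By default every retained cell is weighted equally; `weighting = "area"`
#' weights each cell by its clipped pixel count instead.
#'
#' @param labels Integer label matrix (the full image).
#' @param window Optional window as `c(row, col, size)` (0-based top-left,
#'   pixels) or a one-row data frame with those columns; `NULL` uses the whole
#'   image.
#' @param weighting `"cell"` (equal weight per cell, default) or `"area"`.
#' @param min_inside Minimum fraction of a cell's pixels inside the window.
#' @return A list of class `shape_targets`: `L`, `l` (pixels), `alpha`
#'   (radians in `[0, pi)`), `n_cells`, and `degenerate` (`TRUE` when the two
#'   eigenvalues are numerically equal, in which case `alpha` is set to 0 by
#'   convention).
#' @export
window_shape <- function(labels, window = NULL,
                         weighting = c("cell", "area"), min_inside = 0.5) {
  weighting <- match.arg(weighting)
  if (is.null(window)) {
    sub <- labels
    totals <- NULL # every cell is fully inside
  } else {
    w <- as_window(window)
    if (w["row"] < 0 || w["col"] < 0 ||
      w["row"] + w["size"] > nrow(labels) ||
      w["col"] + w["size"] > ncol(labels)) {
      stop("window does not fit inside the label image")
    }
    sub <- labels[w["row"] + seq_len(w["size"]), w["col"] + seq_len(w["size"]),
      drop = FALSE
    ]
    pos <- labels[labels > 0]
    totals <- tabulate(pos, nbins = max(pos))
  }
  idx <- which(sub > 0)
  if (length(idx) == 0) stop("window contains no cell pixels")
  rc <- arrayInd(idx, dim(sub))
  ids <- sub[idx]
  x <- rc[, 2] - 1
  y <- rc[, 1] - 1

  f <- factor(ids)
  n_i <- as.numeric(rowsum(rep(1, length(ids)), f))
  sx <- as.numeric(rowsum(x, f))
  sy <- as.numeric(rowsum(y, f))
  sxx <- as.numeric(rowsum(x * x, f))
  syy <- as.numeric(rowsum(y * y, f))
  sxy <- as.numeric(rowsum(x * y, f))
  uid <- as.integer(levels(f))

  if (!is.null(totals)) {
    frac <- n_i / totals[uid]
    keep <- frac >= min_inside
    if (!any(keep)) {
      stop(
        "no cell has at least ", min_inside,
        " of its pixels inside the window"
      )
    }
  } else {
    keep <- rep(TRUE, length(uid))
  }

  mxx <- sxx[keep] / n_i[keep] - (sx[keep] / n_i[keep])^2
  myy <- syy[keep] / n_i[keep] - (sy[keep] / n_i[keep])^2
  mxy <- sxy[keep] / n_i[keep] - (sx[keep] / n_i[keep]) * (sy[keep] / n_i[keep])
  wgt <- if (weighting == "cell") rep(1, sum(keep)) else n_i[keep]
  wgt <- wgt / sum(wgt)
  m <- c(sum(mxx * wgt), sum(myy * wgt), sum(mxy * wgt))
  shape_from_moments(m[1], m[2], m[3], n_cells = sum(keep))
}

# eigendecompose an averaged 2x2 moment matrix into shape targets
shape_from_moments <- function(mxx, myy, mxy, n_cells = NA_integer_) {
  tr <- mxx + myy
  disc <- sqrt((mxx - myy)^2 + 4 * mxy^2) # = lambda1 - lambda2 >= 0
  l1 <- (tr + disc) / 2
  l2 <- pmax((tr - disc) / 2, 0)
  degenerate <- disc < 1e-12 * max(tr, .Machine$double.xmin)
  alpha <- if (degenerate) 0 else (0.5 * atan2(2 * mxy, mxx - myy)) %% pi
  structure(
    list(
      L = 4 * sqrt(l1), l = 4 * sqrt(l2), alpha = alpha,
      n_cells = n_cells, degenerate = degenerate
    ),
    class = "shape_targets"
  )
}

#' @export
print.shape_targets <- function(x, ...) {
  cat(sprintf(
    "shape targets: L = %.2f px, l = %.2f px, alpha = %.3f rad%s (%s cells)\n",
    x$L, x$l, x$alpha, if (x$degenerate) " [degenerate]" else "",
    ifelse(is.na(x$n_cells), "?", x$n_cells)
  ))
  invisible(x)
}

as_window <- function(window) {
  if (is.data.frame(window)) {
    window <- c(window$row[1], window$col[1], window$size[1])
  }
  stopifnot(is.numeric(window), length(window) == 3)
  c(row = as.integer(window[1]), col = as.integer(window[2]),
    size = as.integer(window[3]))
}

#' Lay overlapping square windows over an image
#'
#' Windows are placed on a regular grid of stride `round(tile * (1 -
#' overlap))`, 0-based and half-open; when the last regular window does not
#' end exactly at the image edge an extra window clamped to the edge is added,
#' so the whole image is always covered. Windows are returned in row-major
#' order.
#'
#' @param image_shape `c(H, W)` in pixels (a matrix is also accepted).
#' @param tile Window side in pixels (default 128).
#' @param overlap Fraction of overlap between neighbouring windows, in
#'   `[0, 1)`; the coarse-map workflow uses 0.25.
#' @return Data frame with 0-based `row`, `col` origins and `size`.
#' @export
tile_image <- function(image_shape, tile = 128L, overlap = 0) {
  if (is.matrix(image_shape)) image_shape <- dim(image_shape)
  stopifnot(length(image_shape) == 2, overlap >= 0, overlap < 1)
  H <- image_shape[1]
  W <- image_shape[2]
  if (tile > min(H, W)) stop("tile size exceeds image dimensions")
  stride <- max(1L, as.integer(round(tile * (1 - overlap))))
  axis_origins <- function(extent) {
    o <- seq.int(0L, extent - tile, by = stride)
    if (o[length(o)] != extent - tile) o <- c(o, extent - tile)
    o
  }
  ro <- axis_origins(H)
  co <- axis_origins(W)
  data.frame(
    row = rep(ro, each = length(co)),
    col = rep(co, times = length(ro)),
    size = tile
  )
}

#' Tissue anisotropy of a shape measurement
#'
#' Anisotropy is defined as `L / l - 1`: zero for a circular average cell,
#' growing with elongation.
#'
#' @param L Long axis (pixels), or a `shape_targets` object.
#' @param l Short axis (pixels); ignored when `L` is a `shape_targets`.
#' @return Dimensionless anisotropy value(s).
#' @export
anisotropy <- function(L, l = NULL) {
  if (inherits(L, "shape_targets")) {
    l <- L$l
    L <- L$L
  }
  stopifnot(is.numeric(L), is.numeric(l))
  if (any(l <= 0)) stop("anisotropy is undefined for short axis l <= 0")
  L / l - 1
}

#' Per-window ground-truth table for a whole label image
#'
#' Tiles the label image with [tile_image()] and runs [window_shape()] on
#' every window.
#'
#' @inheritParams window_shape
#' @inheritParams tile_image
#' @return Data frame with `tile_id`, `row`, `col`, `L`, `l`, `alpha`,
#'   `anisotropy`, `n_cells`.
#' @export
window_targets <- function(labels, tile = 128L, overlap = 0.25,
                           weighting = c("cell", "area")) {
  weighting <- match.arg(weighting)
  wins <- tile_image(dim(labels), tile, overlap)
  rows <- lapply(seq_len(nrow(wins)), function(i) {
    st <- window_shape(labels, wins[i, ], weighting = weighting)
    data.frame(
      tile_id = i - 1L, row = wins$row[i], col = wins$col[i],
      L = st$L, l = st$l, alpha = st$alpha,
      anisotropy = st$L / st$l - 1, n_cells = st$n_cells
    )
  })
  do.call(rbind, rows)
}
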