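#' Specification of a synthetic confluent tissue
#'
#' Describes a seeded, self-annotated Voronoi tissue: confluent polygonal
#' cells with controllable mean area, elongation (target axis ratio) and
#' orientation field, rendered as thin bright membranes on a dark background
#' (or the inverse) with optional blur and additive gray-level noise. The
#' generator exists so that every downstream stage (ground truth, training,
#' architecture search, mapping) can be exercised end-to-end without any
#' external dataset.
#'
#' @param image_height,image_width Image size in pixels.
#' @param mean_cell_area Target mean cell area in pixels^2; the number of
#'   seeded cells is `round(H * W / mean_cell_area)`.
#' @param stretch_factor Target axis ratio of the generated cells (>= 1);
#'   1 gives isotropic Voronoi cells.
#' @param orientation_mode `"constant"` (all cells at `alpha0`), `"random"`
#'   (each cell gets an independent uniform orientation) or `"smooth"` (a
#'   smooth sinusoidal orientation field around `alpha0` with seeded phases).
#' @param alpha0 Base orientation in radians, used by `"constant"` and
#'   `"smooth"` modes.
#' @param membrane_thickness Membrane thickness in pixels (>= 1; even values
#'   are rendered at the next odd width).
#' @param noise_sigma Additive Gaussian noise sd as a fraction of the gray
#'   range (0 disables).
#' @param blur_sigma Gaussian blur sd in pixels (0 disables).
#' @param invert If `TRUE`, bright cells with dark membranes.
#' @param seed Integer root seed; all stochastic draws derive from it.
#' @return An object of class `tissue_spec`.
#' @export
tissue_spec <- function(image_height = 128L, image_width = 128L,
                        mean_cell_area = 550, stretch_factor = 1,
                        orientation_mode = c("random", "constant", "smooth"),
                        alpha0 = 0, membrane_thickness = 1L,
                        noise_sigma = 0.05, blur_sigma = 1,
                        invert = FALSE, seed = 1L) {
  orientation_mode <- match.arg(orientation_mode)
  stopifnot(
    image_height >= 8, image_width >= 8, mean_cell_area > 0,
    stretch_factor >= 1, membrane_thickness >= 1,
    noise_sigma >= 0, blur_sigma >= 0, is.logical(invert),
    is.numeric(seed), length(seed) == 1
  )
  structure(
    list(
      image_height = as.integer(image_height),
      image_width = as.integer(image_width),
      mean_cell_area = mean_cell_area,
      stretch_factor = stretch_factor,
      orientation_mode = orientation_mode,
      alpha0 = alpha0 %% pi,
      membrane_thickness = as.integer(membrane_thickness),
      noise_sigma = noise_sigma,
      blur_sigma = blur_sigma,
      invert = invert,
      seed = as.integer(seed)
    ),
    class = "tissue_spec"
  )
}

#' Generate a synthetic confluent tissue
#'
#' Cell seed points are drawn from a homogeneous point process; each pixel is
#' assigned to the seed minimizing an anisotropic distance in which the
#' displacement component along the cell's orientation is compressed by the
#' stretch factor, so rendered cells have axis ratio close to
#' `stretch_factor`, oriented per `orientation_mode`. Membrane pixels (label
#' boundaries, dilated to the requested thickness) get label 0 and are drawn
#' bright on dark cell interiors (or inverted); the image is then optionally
#' blurred, noised, and quantized to 8-bit.
#'
#' All randomness derives from `spec$seed`: the R RNG is seeded once and the
#' draws (seed points, orientations, phases, noise) are consumed in a fixed
#' documented order, so identical specs give bitwise-identical outputs.
#'
#' @param spec A [tissue_spec()].
#' @return An object of class `synthetic_tissue`: `image` (numeric matrix,
#'   8-bit gray values 0..255), `labels` (integer matrix, 0 = membrane), and
#'   `cells` (data frame of seed points, orientations and stretch).
#' @export
generate_tissue <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  H <- spec$image_height
  W <- spec$image_width
  n_cells <- round(H * W / spec$mean_cell_area)
  if (n_cells < 4) {
    stop(
      "image too small: ", H, "x", W, " holds only ", n_cells,
      " cells at mean area ", spec$mean_cell_area
    )
  }
  set.seed(spec$seed)
  # draw order: x, y, orientations (mode-dependent), then noise
  x <- stats::runif(n_cells, 0, W - 1)
  y <- stats::runif(n_cells, 0, H - 1)
  ang <- switch(spec$orientation_mode,
    constant = rep(spec$alpha0, n_cells),
    random = stats::runif(n_cells, 0, pi),
    smooth = {
      ph <- stats::runif(2, 0, 2 * pi)
      (spec$alpha0 + 0.35 * pi * sin(2 * pi * x / W + ph[1]) *
        cos(2 * pi * y / H + ph[2])) %% pi
    }
  )
  labels <- cpp_anisotropic_voronoi(
    H, W, cbind(x, y), ang, rep(spec$stretch_factor, n_cells)
  )
  mask <- cpp_boundary_mask(labels)
  if (spec$membrane_thickness > 1) {
    k <- spec$membrane_thickness
    if (k %% 2 == 0) k <- k + 1L
    mask <- EBImage::dilate(
      matrix(as.numeric(mask), H, W),
      EBImage::makeBrush(k, shape = "box")
    ) > 0.5
  }
  labels[mask] <- 0L

  img <- matrix(0, H, W)
  img[mask] <- 1
  if (spec$invert) img <- 1 - img
  if (spec$blur_sigma > 0) {
    img <- EBImage::gblur(img, sigma = spec$blur_sigma)
  }
  if (spec$noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(H * W, 0, spec$noise_sigma), H, W)
  }
  img <- round(pmin(pmax(img, 0), 1) * 255)

  structure(
    list(
      image = img,
      labels = labels,
      cells = data.frame(
        id = seq_len(n_cells), x = x, y = y,
        alpha = ang, stretch = spec$stretch_factor
      ),
      spec = spec
    ),
    class = "synthetic_tissue"
  )
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat(sprintf(
    "synthetic tissue %dx%d px, %d cells, stretch %.2f, orientation %s\n",
    nrow(x$image), ncol(x$image), nrow(x$cells),
    x$spec$stretch_factor, x$spec$orientation_mode
  ))
  invisible(x)
}

#' Generate a tiled training/evaluation dataset of synthetic tissues
#'
#' Each tile is an independent small tissue whose constant orientation is
#' sampled uniformly on `[0, pi)` and whose stretch factor is sampled
#' uniformly from `stretch_range`, so the dataset covers the target space.
#' Targets are computed from each tile's own label image with
#' [window_shape()]. Tiles with fewer than 3 usable cells are regenerated
#' with a derived seed (and a message); the dataset is fully reproducible from
#' `(spec, n_tiles, seed)`.
#'
#' Per-tile seeds derive from the root seed as
#' `(seed + 7919 * tile_index) mod (2^31 - 1)`; regeneration attempts add
#' large fixed offsets.
#'
#' @param spec A [tissue_spec()] template; its seed is the dataset root seed,
#'   its orientation/stretch fields are overridden per tile.
#' @param n_tiles Number of tiles (0 gives an empty dataset).
#' @param tile_size Tile side in pixels (default 128).
#' @param stretch_range Range the per-tile stretch factor is drawn from.
#' @return An object of class `tile_dataset`: `tiles` (numeric matrix,
#'   one flattened tile per row, gray values 0..255), `targets` (data frame
#'   `tile_id`, `row`, `col`, `L`, `l`, `alpha`, `anisotropy`, `n_cells`,
#'   `stretch`), and `tile_size`.
#' @export
make_dataset <- function(spec, n_tiles, tile_size = 128L,
                         stretch_range = c(1, 2.5)) {
  stopifnot(inherits(spec, "tissue_spec"), n_tiles >= 0)
  tiles <- matrix(numeric(0), nrow = 0, ncol = tile_size^2)
  targets <- data.frame(
    tile_id = integer(0), row = integer(0), col = integer(0),
    L = numeric(0), l = numeric(0), alpha = numeric(0),
    anisotropy = numeric(0), n_cells = integer(0), stretch = numeric(0)
  )
  if (n_tiles == 0) {
    return(structure(
      list(tiles = tiles, targets = targets, tile_size = as.integer(tile_size),
           seed = spec$seed),
      class = "tile_dataset"
    ))
  }
  tiles <- matrix(0, nrow = n_tiles, ncol = tile_size^2)
  rows <- vector("list", n_tiles)
  for (i in seq_len(n_tiles)) {
    tile_seed <- (spec$seed + 7919 * i) %% 2147483647
    done <- FALSE
    for (attempt in 0:4) {
      sd_i <- (tile_seed + attempt * 1299709) %% 2147483647
      set.seed(sd_i)
      alpha_i <- stats::runif(1, 0, pi)
      stretch_i <- stats::runif(1, stretch_range[1], stretch_range[2])
      sp <- spec
      sp$image_height <- as.integer(tile_size)
      sp$image_width <- as.integer(tile_size)
      sp$stretch_factor <- stretch_i
      sp$orientation_mode <- "constant"
      sp$alpha0 <- alpha_i
      sp$seed <- as.integer((sd_i + 1) %% 2147483647)
      tis <- generate_tissue(sp)
      st <- tryCatch(window_shape(tis$labels), error = function(e) NULL)
      if (!is.null(st) && st$n_cells >= 3 && !st$degenerate) {
        tiles[i, ] <- as.numeric(tis$image)
        rows[[i]] <- data.frame(
          tile_id = i - 1L, row = 0L, col = 0L,
          L = st$L, l = st$l, alpha = st$alpha,
          anisotropy = st$L / st$l - 1, n_cells = st$n_cells,
          stretch = stretch_i
        )
        done <- TRUE
        break
      }
    }
    if (!done) {
      stop("failed to generate a usable tile after 5 attempts (tile ", i, ")")
    }
    if (done && attempt > 0) {
      message("tile ", i, ": regenerated ", attempt, " time(s)")
    }
  }
  structure(
    list(
      tiles = tiles, targets = do.call(rbind, rows),
      tile_size = as.integer(tile_size), seed = spec$seed
    ),
    class = "tile_dataset"
  )
}

#' @export
print.tile_dataset <- function(x, ...) {
  cat(sprintf(
    "tile dataset: %d tiles of %dx%d px\n",
    nrow(x$tiles), x$tile_size, x$tile_size
  ))
  invisible(x)
}

#' Subset a tile dataset
#'
#' @param ds A `tile_dataset`.
#' @param idx Integer indices of the tiles to keep.
#' @return A `tile_dataset` with the selected tiles.
#' @export
dataset_subset <- function(ds, idx) {
  stopifnot(inherits(ds, "tile_dataset"))
  structure(
    list(
      tiles = ds$tiles[idx, , drop = FALSE],
      targets = ds$targets[idx, , drop = FALSE],
      tile_size = ds$tile_size, seed = ds$seed
    ),
    class = "tile_dataset"
  )
}
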