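#' Write a synthetic tissue to disk
#'
#' The membrane image is written as 8-bit grayscale PNG, the label image as
#' 16-bit grayscale TIFF, and the per-cell parameters as CSV.
#'
#' @param tissue A `synthetic_tissue`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_tissue <- function(tissue, dir, prefix = "tissue") {
  stopifnot(inherits(tissue, "synthetic_tissue"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  img_path <- file.path(dir, paste0(prefix, ".png"))
  lab_path <- file.path(dir, paste0(prefix, "_labels.tif"))
  cell_path <- file.path(dir, paste0(prefix, "_cells.csv"))
  png::writePNG(tissue$image / 255, img_path)
  if (max(tissue$labels) > 65535) stop("more than 65535 cells; 16-bit labels overflow")
  tiff::writeTIFF(tissue$labels / 65535, lab_path, bits.per.sample = 16L)
  utils::write.csv(tissue$cells, cell_path, row.names = FALSE)
  invisible(c(image = img_path, labels = lab_path, cells = cell_path))
}

#' Read a 16-bit TIFF label image back as an integer matrix
#'
#' @param path Path to a label TIFF written by [write_tissue()] (or any
#'   16-bit single-channel label raster).
#' @return Integer matrix of cell IDs (0 = boundary/background).
#' @export
read_label_image <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  matrix(as.integer(round(x * 65535)), nrow(x), ncol(x))
}

#' Read an 8-bit grayscale image (PNG or TIFF) as a 0..255 matrix
#'
#' @param path Image path; `.png`/`.tif`/`.tiff` are recognized.
#' @return Numeric matrix of gray values in 0..255.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image extension: ", ext)
  )
  if (length(dim(x)) == 3) x <- x[, , 1]
  round(x * 255)
}

#' Write / read per-window shape-target tables
#'
#' @param targets Data frame of targets (e.g. from [window_targets()] or a
#'   `tile_dataset`); written with the `tile_id,row,col,L,l,alpha,...` header.
#' @param path CSV path.
#' @export
write_targets_csv <- function(targets, path) {
  utils::write.csv(targets, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_targets_csv
#' @export
read_targets_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
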