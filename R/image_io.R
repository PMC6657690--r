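# Reading, writing and preprocessing of cross-section images and label maps.
#
# The canonical in-memory representation of an intensity image is a plain
# numeric matrix of 8-bit values in [0, 255], indexed (row, col) with the
# origin at the top-left. Higher bit depths are linearly rescaled on load and
# colour inputs are converted to luminance.

#' Load an image as canonical 8-bit grayscale
#'
#' Reads a PNG or TIFF (single- or 3-channel). RGB images are converted to
#' luminance with the Rec. 601 weights (0.299, 0.587, 0.114); images of
#' higher bit depth are linearly rescaled so that the maximum representable
#' value maps to 255.
#'
#' @param path file path to a PNG or TIFF image.
#' @return numeric matrix of intensities in [0, 255].
#' @export
load_grayscale <- function(path) {
  if (!file.exists(path)) stop_fs("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_fs("unsupported image format (need .png/.tif/.tiff): ", path)
  )
  if (length(dim(raw)) == 3L) {
    nc <- dim(raw)[3]
    if (nc >= 3L) {
      raw <- 0.299 * raw[, , 1] + 0.587 * raw[, , 2] + 0.114 * raw[, , 3]
    } else {
      raw <- raw[, , 1]
    }
  }
  if (nrow(raw) < 1L || ncol(raw) < 1L) stop_fs("zero-sized image: ", path)
  # readPNG/readTIFF scale to [0,1] regardless of source bit depth
  img <- round(pmin(pmax(raw, 0), 1) * 255)
  assert_image(img)
}

#' Write an 8-bit grayscale image
#'
#' @param img numeric matrix in [0, 255].
#' @param path output path ending in .png, .tif or .tiff.
#' @return the path, invisibly.
#' @export
write_grayscale <- function(img, path) {
  assert_image(img)
  ext <- tolower(tools::file_ext(path))
  x <- img / 255
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop_fs("unsupported image format (need .png/.tif/.tiff): ", path)
  )
  invisible(path)
}

#' Preprocessing configuration
#'
#' Holds the manual intensity threshold applied before segmentation: pixels
#' below `tau_intensity` are set to zero so that dark interstitial (gap)
#' regions are excluded from cell detection. Distinct from the
#' distance-transform threshold of [separation_config()].
#'
#' @param tau_intensity integer threshold in [0, 255]; 0 disables.
#' @return a list of class `fs_preprocess_config`.
#' @export
preprocess_config <- function(tau_intensity = 0L) {
  assert_scalar_in(tau_intensity, 0, 255, "tau_intensity")
  structure(list(tau_intensity = as.numeric(tau_intensity)),
            class = "fs_preprocess_config")
}

#' Apply the manual intensity threshold
#'
#' Keeps pixel values greater than or equal to the threshold and zeroes the
#' rest: `I(x,y) = Ihat(x,y)` if `Ihat(x,y) >= tau`, else 0. Idempotent, and
#' monotone in the threshold.
#'
#' @param img numeric matrix in [0, 255].
#' @param cfg a [preprocess_config()].
#' @return thresholded image, same dimensions.
#' @export
apply_intensity_threshold <- function(img, cfg = preprocess_config()) {
  assert_image(img)
  stopifnot(inherits(cfg, "fs_preprocess_config"))
  out <- img
  out[img < cfg$tau_intensity] <- 0
  out
}

#' Write a fibre measurement table
#'
#' Writes a CSV with the fixed header
#' `fibre_id,area,feret,centroid_row,centroid_col,perimeter`, rows ordered
#' by fibre_id.
#'
#' @param rows data frame with the columns above (e.g. from
#'   [measure_fibre()] / [fibre_table()]).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_fibre_table <- function(rows, path) {
  cols <- c("fibre_id", "area", "feret", "centroid_row", "centroid_col",
            "perimeter")
  if (nrow(rows) == 0L) {
    rows <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  if (!all(cols %in% names(rows))) {
    stop_fs("fibre table must have columns: ", paste(cols, collapse = ", "))
  }
  rows <- as.data.frame(rows)[order(rows$fibre_id), cols, drop = FALSE]
  ok <- tryCatch({
    write.csv(rows, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_fs("cannot write fibre table to: ", path)
  invisible(path)
}

#' Read and write label images
#'
#' Label images hold nonnegative integer object labels; 0 is background.
#' They are stored losslessly as 16-bit single-channel TIFF (PNG accepted on
#' read; on write, PNG output is limited to 8-bit label ranges).
#'
#' @param lab integer matrix of labels in [0, 65535].
#' @param path file path (.tif/.tiff, or .png for labels <= 255).
#' @return `write_label_image()` the path invisibly; `read_label_image()` an
#'   integer matrix.
#' @export
write_label_image <- function(lab, path) {
  assert_labels(lab)
  if (max(lab) > 65535) stop_fs("labels exceed 65535; cannot store as 16-bit")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (max(lab) > 255) {
      stop_fs("PNG label output supports labels <= 255; use .tif for 16-bit")
    }
    png::writePNG(lab / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
  } else {
    stop_fs("unsupported label format (need .png/.tif/.tiff): ", path)
  }
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(path) {
  if (!file.exists(path)) stop_fs("cannot read label image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    bits <- attr(raw, "info")$bit.depth
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(raw, "bits.per.sample")
  } else {
    stop_fs("unsupported label format (need .png/.tif/.tiff): ", path)
  }
  if (is.null(bits)) bits <- 16L
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  v <- round(raw * (2^bits - 1))
  matrix(as.integer(v), nrow(raw), ncol(raw))
}
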