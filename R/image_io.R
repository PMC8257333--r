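# Image and mask I/O.
#
# Images are plain numeric matrices (rows x cols, 1-based indexing) with
# intensities on the 8-bit scale [0, 255]; masks are logical matrices of the
# same shape. PNG is the lossless workhorse; JPEG is accepted on input
# because clinical angiography exports commonly use it. TIFF is not
# supported (no reader available in the dependency set).

#' Read a grayscale image
#'
#' Loads a PNG or JPEG file as a numeric intensity matrix on the
#' \[0, 255\] scale. Multi-channel images are converted to luminance by the
#' unweighted channel mean (so an RGB image with identical channels maps
#' exactly onto its single channel); an alpha channel, if present, is
#' dropped before averaging.
#'
#' @param path Path to a `.png`, `.jpg`/`.jpeg` file.
#' @return Numeric matrix (height x width) with values in \[0, 255\].
#' @examples
#' img <- make_phantom(phantom_spec(height = 32, width = 32))$image
#' f <- tempfile(fileext = ".png")
#' write_gray_image(img, f)
#' round_trip <- read_gray_image(f)
#' @export
read_gray_image <- function(path) {
  arr <- read_image_array(path)
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    if (nc %in% c(2L, 4L)) {
      # gray+alpha or RGBA: drop alpha
      arr <- arr[, , seq_len(nc - 1L), drop = FALSE]
    }
    img <- rowMeans(arr, dims = 2L)
  } else {
    img <- arr
  }
  img <- img * 255
  if (nrow(img) < 2L || ncol(img) < 2L) {
    stop_validation("image at ", path, " is smaller than 2x2 pixels")
  }
  check_gray_image(img, "image")
  img
}

read_image_array <- function(path) {
  if (!file.exists(path)) stop_io("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop_io("unsupported image format '.", ext,
            "' (supported: png, jpg/jpeg)")
  )
  if (length(arr) == 0L) stop_validation("zero-area image: ", path)
  arr
}

#' Write a grayscale image as 8-bit PNG
#'
#' Intensities are rounded to the nearest integer gray level; the written
#' file round-trips exactly through [read_gray_image()] for integer-valued
#' inputs.
#'
#' @param image Numeric matrix with values in \[0, 255\].
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  check_gray_image(image)
  png::writePNG(round(image) / 255, target = path)
  invisible(path)
}

#' Read a binary mask
#'
#' A mask file is expected to contain at most two distinct gray levels, in
#' which case any nonzero pixel is in-region. Files with more than two
#' distinct levels are rejected unless an explicit `threshold` is supplied,
#' in which case pixels strictly above it (8-bit scale) are in-region; the
#' natural midpoint for 8-bit data is 127.5.
#'
#' @param path Path to a PNG/JPEG mask file.
#' @param threshold Optional numeric cut on the \[0, 255\] scale.
#' @return Logical matrix (`TRUE` = in-region).
#' @export
read_mask <- function(path, threshold = NULL) {
  img <- read_gray_image(path)
  vals <- unique(as.numeric(img))
  if (length(vals) > 2L) {
    if (is.null(threshold)) {
      stop_validation("mask at ", path, " has ", length(vals),
                      " distinct gray levels; pass threshold= to binarize")
    }
    check_scalar_number(threshold, "threshold")
    return(img > threshold)
  }
  img != 0
}

#' Write a binary mask as 8-bit PNG (0 / 255)
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly. `read_mask(write_mask(m, f))` reproduces `m`.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  png::writePNG(ifelse(mask, 1, 0), target = path)
  invisible(path)
}

#' Write an integer label map as 8-bit PNG
#'
#' Region index becomes the pixel gray level (0 = background); label maps
#' with more than 255 regions are rejected.
#'
#' @param labels Integer matrix of region labels, 0-based background.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  if (!is.matrix(labels) || !is.numeric(labels)) {
    stop_validation("labels must be an integer matrix")
  }
  if (max(labels) > 255 || min(labels) < 0) {
    stop_validation("label values must lie in [0, 255] to be PNG-encodable")
  }
  png::writePNG(labels / 255, target = path)
  invisible(path)
}
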