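#' Grayscale microscopy image
#'
#' Container for a single-channel 8- or 16-bit microscopy image of thrombi
#' formed in a flow chamber. Pixels are stored as a numeric matrix in
#' original intensity units (0 .. 2^bit_depth - 1); intermediate processing
#' keeps floating point and only the final outputs are rounded/clipped.
#'
#' @param pixels numeric matrix of non-negative intensities (rows = image
#'   rows, origin top-left).
#' @param bit_depth integer, 8 or 16.
#' @param pixel_size_um optional micrometers per pixel.
#' @param channel one of `"brightfield"`, `"annexinA5"`, `"CD62P"`, `"JONA"`.
#' @return an object of class `gray_image`.
#' @examples
#' img <- gray_image(matrix(120, 64, 64), bit_depth = 8)
#' dim(img)
#' @export
gray_image <- function(pixels, bit_depth = 8L,
                       pixel_size_um = NULL,
                       channel = c("brightfield", "annexinA5", "CD62P", "JONA")) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix (non-rectangular input is invalid)",
         call. = FALSE)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
  if (any(!is.finite(pixels))) stop("pixel intensities must be finite", call. = FALSE)
  maxval <- 2^bit_depth - 1
  if (min(pixels) < 0 || max(pixels) > maxval)
    stop(sprintf("intensities must lie in [0, %d] for bit depth %d", maxval, bit_depth),
         call. = FALSE)
  if (any(dim(pixels) < 8))
    stop("image too small: both dimensions must be >= 8 (>= 64 recommended)",
         call. = FALSE)
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 pixel_size_um = pixel_size_um, channel = channel),
            class = "gray_image")
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, %d-bit, channel %s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$channel))
  cat(sprintf("  intensity range [%.1f, %.1f], mean %.2f\n",
              min(x$pixels), max(x$pixels), mean(x$pixels)))
  invisible(x)
}

#' Binary segmentation mask
#'
#' @param pixels logical matrix, `TRUE` where platelet material was detected.
#' @param source_threshold the intensity threshold that produced the mask,
#'   recorded because manually chosen thresholds are the main
#'   reproducibility hazard of this analysis.
#' @return object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, source_threshold = NA_real_) {
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("'pixels' must be a logical matrix", call. = FALSE)
  if (any(is.na(pixels))) stop("mask must not contain NA", call. = FALSE)
  structure(list(pixels = pixels, source_threshold = source_threshold),
            class = "binary_mask")
}

#' @export
dim.binary_mask <- function(x) dim(x$pixels)

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d, %.2f%% foreground (threshold %s)\n",
              nrow(x$pixels), ncol(x$pixels), 100 * mean(x$pixels),
              format(x$source_threshold)))
  invisible(x)
}

# clip to bit-depth range and keep floating point
clip_intensity <- function(px, bit_depth) {
  pmin(pmax(px, 0), 2^bit_depth - 1)
}

#' Read a grayscale image from TIFF or PNG
#'
#' Single-channel 8/16-bit TIFF (stripped or tiled) and PNG are supported;
#' multi-channel files are averaged to one channel with a warning. Intensities
#' are rescaled from the readers' [0, 1] convention back to integer units.
#'
#' @param path file path; format chosen by extension (.tif/.tiff/.png).
#' @param bit_depth bit depth of the stored data; if `NULL`, inferred from
#'   the file (PNG/TIFF metadata, falling back to 8).
#' @inheritParams gray_image
#' @return a [gray_image()].
#' @export
read_gray_image <- function(path, bit_depth = NULL, channel = "brightfield",
                            pixel_size_um = NULL) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, as.is = TRUE)
    if (is.null(bit_depth)) bit_depth <- if (max(raw) > 255) 16L else 8L
    px <- raw
  } else if (ext == "png") {
    raw <- png::readPNG(path)
    if (is.null(bit_depth)) bit_depth <- 8L
    px <- raw * (2^bit_depth - 1)
  } else stop("unsupported image format: .", ext, call. = FALSE)
  if (length(dim(px)) == 3L) {
    warning("multi-channel image collapsed to grayscale by averaging")
    px <- apply(px, c(1, 2), mean)
  }
  gray_image(round(px), bit_depth = bit_depth, channel = channel,
             pixel_size_um = pixel_size_um)
}

#' Write a binary mask as an 8-bit TIFF (0/255)
#'
#' @param mask a [binary_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  tiff::writeTIFF(ifelse(mask$pixels, 1, 0), path, bits.per.sample = 8L)
  invisible(path)
}
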