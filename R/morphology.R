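#' Morphology and bandpass configuration
#'
#' Parameters of the brightfield clean-up sequence (a large diamond-shaped
#' grayscale closing, a medium disc closing, then a small disc dilation) and
#' of the FFT bandpass background correction. The closings bridge the 1-2 px
#' striping typical of enhanced-contrast CCD brightfield recordings at 60x/63x
#' magnification; the bandpass suppresses structures larger than
#' `bandpass_large_px` (60 px for brightfield, 65 px for fluorescence
#' channels). Fine structure is never filtered away: it carries the platelet
#' detail of interest, so `bandpass_small_px` is off by default.
#'
#' @param large_diamond_radius_px radius of the diamond closing element.
#' @param medium_circle_radius_px radius of the disc closing element.
#' @param small_circle_radius_px radius of the final disc dilation element.
#' @param bandpass_large_px spatial scale (px) above which intensity
#'   variation is suppressed.
#' @param bandpass_small_px optional scale below which variation is
#'   suppressed (`NULL` = keep all fine structure).
#' @return object of class `morphology_config`.
#' @examples
#' morphology_config()                       # brightfield defaults
#' morphology_config(bandpass_large_px = 65) # fluorescence channels
#' @export
morphology_config <- function(large_diamond_radius_px = 4L,
                              medium_circle_radius_px = 2L,
                              small_circle_radius_px = 1L,
                              bandpass_large_px = 60L,
                              bandpass_small_px = NULL) {
  r <- c(large_diamond_radius_px, medium_circle_radius_px, small_circle_radius_px)
  if (any(r != round(r)) || r[3] < 1)
    stop("structuring-element radii must be integers >= 1", call. = FALSE)
  if (!(r[1] > r[2] && r[2] > r[3]))
    stop("config error: radii must satisfy large > medium > small >= 1",
         call. = FALSE)
  if (bandpass_large_px < 2) stop("bandpass_large_px must be >= 2", call. = FALSE)
  if (!is.null(bandpass_small_px) && bandpass_small_px >= bandpass_large_px)
    stop("bandpass_small_px must be smaller than bandpass_large_px", call. = FALSE)
  structure(list(large_diamond_radius_px = as.integer(r[1]),
                 medium_circle_radius_px = as.integer(r[2]),
                 small_circle_radius_px = as.integer(r[3]),
                 bandpass_large_px = as.integer(bandpass_large_px),
                 bandpass_small_px = bandpass_small_px),
            class = "morphology_config")
}

#' @export
print.morphology_config <- function(x, ...) {
  cat("<morphology_config>\n")
  cat(sprintf("  close: diamond r=%d, disc r=%d; dilate: disc r=%d\n",
              x$large_diamond_radius_px, x$medium_circle_radius_px,
              x$small_circle_radius_px))
  cat(sprintf("  bandpass: large %d px, small %s\n", x$bandpass_large_px,
              if (is.null(x$bandpass_small_px)) "off" else x$bandpass_small_px))
  invisible(x)
}

# structuring elements delegated to EBImage brushes (odd-sized, centered)
se_brush <- function(radius, shape) EBImage::makeBrush(2L * radius + 1L, shape)

# grayscale morphology on intensity matrices; EBImage operates on [0,1]
morph_op <- function(px, bit_depth, kern, op = c("dilate", "erode", "close")) {
  op <- match.arg(op)
  maxval <- 2^bit_depth - 1
  x <- px / maxval
  y <- switch(op,
              dilate = EBImage::dilate(x, kern),
              erode  = EBImage::erode(x, kern),
              close  = EBImage::closing(x, kern))
  y * maxval
}

#' Brightfield grayscale morphology clean-up
#'
#' Applies, in order, a grayscale closing with a diamond element, a grayscale
#' closing with a medium disc, and a grayscale dilation with a small disc.
#' The first closing lifts pixels in densely covered regions and removes dark
#' striping narrower than the diamond; the second rounds shapes and further
#' suppresses straight lines; the final dilation consolidates the bright
#' structures. Output dimensions are unchanged and intensities are clipped to
#' the bit-depth range.
#'
#' @param img a [gray_image()].
#' @param cfg a [morphology_config()].
#' @return a `gray_image` of identical dimensions.
#' @seealso [quantify_brightfield()] for the full quantification chain.
#' @export
morph_clean_brightfield <- function(img, cfg = morphology_config()) {
  stopifnot(inherits(img, "gray_image"), inherits(cfg, "morphology_config"))
  px <- morph_op(img$pixels, img$bit_depth,
                 se_brush(cfg$large_diamond_radius_px, "diamond"), "close")
  px <- morph_op(px, img$bit_depth,
                 se_brush(cfg$medium_circle_radius_px, "disc"), "close")
  px <- morph_op(px, img$bit_depth,
                 se_brush(cfg$small_circle_radius_px, "disc"), "dilate")
  out <- img
  out$pixels <- clip_intensity(px, img$bit_depth)
  out
}
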