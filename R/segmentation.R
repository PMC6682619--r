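#' Threshold an image into a platelet mask
#'
#' For fluorescence channels foreground is intensity above the threshold; for
#' brightfield the foreground is the side of the threshold holding the object
#' class, controlled by `polarity`. With `threshold = "auto"` the threshold is
#' resolved by Otsu's criterion on the image histogram and the resolved value
#' is recorded in the mask's `source_threshold`.
#'
#' A plain Otsu split of a featureless image lands in the middle of the
#' noise, so automatic thresholding applies a minimum-contrast guard: when
#' the separation between the two class means is below `min_contrast_frac`
#' of the dynamic range, the image is declared background-only and an empty
#' mask is returned (the resolved threshold is still recorded).
#'
#' @param img a [gray_image()], normally background-corrected (and, for
#'   brightfield, morphology-cleaned) first.
#' @param threshold numeric intensity or `"auto"`.
#' @param polarity `"bright_objects"`, `"dark_objects"`, or `"auto"`
#'   (the minority pixel class after an Otsu split). Fluorescence channels
#'   default to bright objects.
#' @param min_contrast_frac minimum class-mean separation, as a fraction of
#'   the dynamic range, for an automatic threshold to be trusted.
#' @return a [binary_mask()] with the same dimensions as `img`.
#' @export
segment <- function(img, threshold = "auto",
                    polarity = c("auto", "bright_objects", "dark_objects"),
                    min_contrast_frac = 0.05) {
  stopifnot(inherits(img, "gray_image"))
  polarity <- match.arg(polarity)
  px <- img$pixels
  maxval <- 2^img$bit_depth - 1
  if (img$channel != "brightfield" && polarity == "auto")
    polarity <- "bright_objects"

  auto <- identical(threshold, "auto")
  if (auto) {
    thr <- otsu_threshold(px, img$bit_depth)
  } else {
    thr <- as.numeric(threshold)
    if (!is.finite(thr) || thr < 0 || thr > maxval)
      stop("invalid input: threshold outside the bit-depth range [0, ",
           maxval, "]", call. = FALSE)
  }

  hi <- px > thr
  if (polarity == "auto")
    polarity <- if (mean(hi) <= 0.5) "bright_objects" else "dark_objects"
  fg <- if (polarity == "bright_objects") hi else px < thr

  if (auto) {
    # contrast guard: reject splits that only partition the noise
    sep <- abs(mean(px[hi]) - mean(px[!hi]))
    if (!is.finite(sep) || sep < min_contrast_frac * maxval)
      fg[] <- FALSE
  }
  m <- binary_mask(fg, source_threshold = thr)
  attr(m, "polarity") <- polarity
  m
}

# Otsu's threshold via EBImage on the [0,1] scale
otsu_threshold <- function(px, bit_depth) {
  maxval <- 2^bit_depth - 1
  EBImage::otsu(px / maxval, range = c(0, 1),
                levels = 2^bit_depth) * maxval
}

#' Surface area coverage of a mask
#'
#' The central readout of the flow-chamber assay: the percentage of the image
#' area covered by platelet material (%SAC).
#'
#' @param mask a [binary_mask()].
#' @return coverage percentage in [0, 100].
#' @examples
#' m <- binary_mask(matrix(c(rep(TRUE, 37), rep(FALSE, 63)), 10, 10))
#' surface_area_coverage(m)  # 37
#' @export
surface_area_coverage <- function(mask) {
  if (!inherits(mask, "binary_mask"))
    stop("invalid input: not a binary_mask", call. = FALSE)
  if (length(mask$pixels) == 0)
    stop("invalid input: empty mask object", call. = FALSE)
  100 * mean(mask$pixels)
}

#' Platelet aggregate coverage (%SAC of multilayered regions)
#'
#' Extracts the aggregate subset of a platelet mask with a two-criterion
#' rule: a connected foreground component counts as an aggregate when it
#' (i) exceeds `min_area_px` and (ii) passes a second, more stringent
#' contrast threshold capturing multilayered regions (at least
#' `min_stringent_frac` of its pixels beyond that threshold). Adhered single
#' platelets are a few pixels across and fail the area criterion; monolayer
#' sheets fail the contrast criterion. By construction aggregate %SAC never
#' exceeds platelet %SAC.
#'
#' With `stringent_threshold = "auto"` the threshold is a second Otsu split
#' computed within the platelet foreground only, subject to the same
#' minimum-contrast guard as [segment()] (a homogeneous monolayer yields no
#' aggregates rather than a noise split).
#'
#' @param img the processed [gray_image()] the mask was derived from.
#' @param platelet_mask a [binary_mask()] from [segment()].
#' @param min_area_px minimum component area in pixels.
#' @param stringent_threshold numeric intensity or `"auto"`; must be at
#'   least as strict as the mask's own threshold.
#' @param min_stringent_frac fraction of component pixels that must pass the
#'   stringent threshold.
#' @param min_contrast_frac contrast guard for the automatic stringent split.
#' @return list with `aggregate_percent`, `aggregate_mask` (a
#'   [binary_mask()]), and the resolved `stringent_threshold`.
#' @export
aggregate_coverage <- function(img, platelet_mask, min_area_px = 80,
                               stringent_threshold = "auto",
                               min_stringent_frac = 0.3,
                               min_contrast_frac = 0.05) {
  stopifnot(inherits(img, "gray_image"), inherits(platelet_mask, "binary_mask"))
  if (!identical(dim(img$pixels), dim(platelet_mask$pixels)))
    stop("mask and image dimensions differ", call. = FALSE)
  maxval <- 2^img$bit_depth - 1
  pol <- attr(platelet_mask, "polarity")
  # work on a bright-objects axis so "more stringent" always means "greater"
  v <- if (identical(pol, "dark_objects")) maxval - img$pixels else img$pixels
  thr0 <- platelet_mask$source_threshold
  if (identical(pol, "dark_objects") && is.finite(thr0)) thr0 <- maxval - thr0

  empty <- binary_mask(matrix(FALSE, nrow(v), ncol(v)), NA_real_)
  fg <- platelet_mask$pixels
  if (!any(fg))
    return(list(aggregate_percent = 0, aggregate_mask = empty,
                stringent_threshold = NA_real_))

  if (identical(stringent_threshold, "auto")) {
    vals <- v[fg]
    thr2 <- otsu_threshold(matrix(vals, nrow = 1), img$bit_depth)
    sep <- abs(mean(vals[vals > thr2]) - mean(vals[vals <= thr2]))
    if (!is.finite(sep) || sep < min_contrast_frac * maxval)
      return(list(aggregate_percent = 0, aggregate_mask = empty,
                  stringent_threshold = thr2))
  } else {
    thr2 <- as.numeric(stringent_threshold)
    if (identical(pol, "dark_objects")) thr2 <- maxval - thr2
    if (is.finite(thr0) && thr2 < thr0)
      stop("config error: stringent threshold is less strict than the ",
           "primary segmentation threshold", call. = FALSE)
  }

  lab <- EBImage::bwlabel(fg * 1)
  ids <- seq_len(max(lab))
  if (length(ids) == 0)
    return(list(aggregate_percent = 0, aggregate_mask = empty,
                stringent_threshold = thr2))
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  pass <- tabulate(lab[lab > 0 & v > thr2], nbins = max(lab))
  keep <- which(areas >= min_area_px & pass / areas >= min_stringent_frac)
  agg <- matrix(lab %in% keep, nrow(v), ncol(v))
  list(aggregate_percent = 100 * mean(agg),
       aggregate_mask = binary_mask(agg, source_threshold = thr2),
       stringent_threshold = thr2)
}

#' Quantify a brightfield thrombus image
#'
#' The full brightfield chain: FFT bandpass background correction, grayscale
#' morphology clean-up, automatic (or manual) thresholding, and surface-area
#' coverage of platelets (P1) and aggregates (P2).
#'
#' The morphology sequence is essential for robust threshold detection (it
#' suppresses striping that can derail an automatic threshold), but its
#' closings and final dilation are extensive: they bridge narrow gaps
#' between adjacent platelets and grow every object, which would bias
#' coverage upward. With `remeasure_on_corrected = TRUE` (default) the mask
#' detected on the cleaned image is therefore re-measured against the
#' bandpass-corrected (un-cleaned) intensities: the detected threshold is
#' shifted by the morphology-induced background lift (the median raise of
#' background pixels) and then refined to the flattest point of the
#' coverage-vs-threshold curve, which lies in the intensity gap between the
#' background and platelet classes. Bridge and halo pixels sit at background
#' intensity in the bandpass image and are excluded; true platelet pixels
#' are retained.
#'
#' @inheritParams segment
#' @inheritParams aggregate_coverage
#' @param cfg a [morphology_config()].
#' @param remeasure_on_corrected re-measure the detected mask on the
#'   bandpass-corrected intensities (unbiased coverage; see Details).
#' @return list with `sac_percent` (P1), `aggregate_percent` (P2), the
#'   resolved `threshold`, `mask`, `aggregate_mask`, and the `processed`
#'   image.
#' @export
quantify_brightfield <- function(img, cfg = morphology_config(),
                                 threshold = "auto", polarity = "auto",
                                 remeasure_on_corrected = TRUE,
                                 min_area_px = 80,
                                 stringent_threshold = "auto") {
  stopifnot(inherits(img, "gray_image"))
  bp <- bandpass_correct(img, cfg)
  proc <- morph_clean_brightfield(bp, cfg)
  mask <- segment(proc, threshold = threshold, polarity = polarity)
  if (remeasure_on_corrected && any(mask$pixels) && !all(mask$pixels)) {
    dark <- identical(attr(mask, "polarity"), "dark_objects")
    # work on a bright-objects axis; morphology is extensive, so background
    # pixels are lifted by >= 0 on that axis
    maxval <- 2^img$bit_depth - 1
    v <- if (dark) maxval - bp$pixels else bp$pixels
    vproc <- if (dark) maxval - proc$pixels else proc$pixels
    thr <- if (dark) maxval - mask$source_threshold else mask$source_threshold
    lift <- stats::median((vproc - v)[!mask$pixels])
    t0 <- thr - lift
    # refine within the class gap: the coverage-vs-threshold curve is
    # flattest between the background and platelet intensity modes
    cand <- t0 + seq(-0.04, 0.06, by = 0.005) * maxval
    A <- vapply(cand, function(t) mean(mask$pixels & (v > t)), 0)
    steep <- abs(diff(A, lag = 2))
    mid <- cand[-c(1, length(cand))]
    tstar <- mid[order(steep, abs(mid - t0))][1]
    mask$pixels <- mask$pixels & (v > tstar)
  }
  agg <- aggregate_coverage(proc, mask, min_area_px = min_area_px,
                            stringent_threshold = stringent_threshold)
  list(sac_percent = surface_area_coverage(mask),
       aggregate_percent = agg$aggregate_percent,
       threshold = mask$source_threshold,
       mask = mask, aggregate_mask = agg$aggregate_mask,
       processed = proc)
}

#' Quantify a fluorescence channel image
#'
#' Background correction (large-structure scale 65 px by default) followed by
#' thresholding; returns the %SAC of the stained marker (P6, P7 or P8
#' depending on the channel).
#'
#' @inheritParams quantify_brightfield
#' @export
quantify_fluorescence <- function(img,
                                  cfg = morphology_config(bandpass_large_px = 65),
                                  threshold = "auto") {
  stopifnot(inherits(img, "gray_image"))
  proc <- bandpass_correct(img, cfg)
  mask <- segment(proc, threshold = threshold, polarity = "bright_objects")
  list(sac_percent = surface_area_coverage(mask),
       threshold = mask$source_threshold, mask = mask, processed = proc)
}
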