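#' Per-image thrombus parameters
#'
#' Bundles the up-to-eight parameters measured on one image set: platelet
#' %SAC (P1) and aggregate %SAC (P2) from brightfield, the visual thrombus
#' morphology (P3, 0-5), multilayer (P4, 0-3) and contraction (P5, 0-3)
#' scores, and the fluorescence activation %SACs for PS exposure (P6),
#' P-selectin (P7) and activated integrin aIIbb3 (P8). Missing parameters
#' (e.g. unavailable fluorescence channels) are `NA`.
#'
#' Validation enforces the parameter ranges, half-step increments for the
#' visual scores, and P2 <= P1 whenever both are present.
#'
#' @param P1,P2,P3,P4,P5,P6,P7,P8 parameter values or `NA`.
#' @param surface microspot, one of `"M1"` (collagen-I), `"M2"`
#'   (rhodocytin/laminin/VWF-BP), `"M3"` (laminin/VWF-BP).
#' @param image_id identifier of the image (set).
#' @return object of class `image_parameters`.
#' @export
image_parameters <- function(P1 = NA, P2 = NA, P3 = NA, P4 = NA, P5 = NA,
                             P6 = NA, P7 = NA, P8 = NA,
                             surface = c("M1", "M2", "M3"),
                             image_id = NA_character_) {
  surface <- match.arg(surface)
  p <- c(P1 = P1, P2 = P2, P3 = P3, P4 = P4, P5 = P5, P6 = P6, P7 = P7, P8 = P8)
  validate_parameters(p)
  structure(list(values = p, surface = surface, image_id = image_id),
            class = "image_parameters")
}

validate_parameters <- function(p) {
  rng <- parameter_ranges()
  for (nm in names(p)) {
    v <- p[[nm]]
    if (is.na(v)) next
    r <- rng[[nm]]
    if (v < r[1] || v > r[2])
      stop(sprintf("%s = %g outside its valid range [%g, %g]", nm, v, r[1], r[2]),
           call. = FALSE)
    if (nm %in% visual_scores() && abs(v * 2 - round(v * 2)) > 1e-8)
      stop(sprintf("%s = %g: visual scores are assigned in 0.5 increments", nm, v),
           call. = FALSE)
  }
  if (!is.na(p[["P1"]]) && !is.na(p[["P2"]]) && p[["P2"]] > p[["P1"]] + 1e-9)
    stop("aggregate coverage P2 cannot exceed platelet coverage P1", call. = FALSE)
  invisible(p)
}

#' @export
print.image_parameters <- function(x, ...) {
  cat(sprintf("<image_parameters> %s, surface %s\n",
              x$image_id, x$surface))
  print(round(x$values, 3))
  invisible(x)
}

#' Average image parameters over one experiment
#'
#' Parameter values from the (typically three) images of one perfusion
#' experiment are averaged into a single value per parameter. A parameter
#' present in only a subset of the images is averaged over the available
#' images with a warning; it stays missing only if absent everywhere. All
#' images must come from the same microspot surface.
#'
#' @param images list of [image_parameters()].
#' @return an `image_parameters` object holding the per-parameter means.
#' @examples
#' imgs <- lapply(c(10, 20, 30), function(v) image_parameters(P1 = v))
#' average_experiment(imgs)$values[["P1"]]  # 20
#' @export
average_experiment <- function(images) {
  if (length(images) < 1) stop("invalid input: no images", call. = FALSE)
  stopifnot(all(vapply(images, inherits, TRUE, "image_parameters")))
  surfaces <- unique(vapply(images, `[[`, "", "surface"))
  if (length(surfaces) != 1)
    stop("invalid input: images from mixed surfaces (", paste(surfaces, collapse = ", "),
         ")", call. = FALSE)
  vals <- do.call(rbind, lapply(images, function(x) x$values))
  n_avail <- colSums(!is.na(vals))
  partial <- names(which(n_avail > 0 & n_avail < nrow(vals)))
  if (length(partial))
    warning("parameter(s) ", paste(partial, collapse = ", "),
            " present in only a subset of images; averaged over available images")
  m <- colMeans(vals, na.rm = TRUE)
  m[n_avail == 0] <- NA
  out <- images[[1]]
  out$values <- m
  out$image_id <- paste0("mean_of_", nrow(vals))
  validate_parameters(m)
  out
}

#' Assemble an experiment table
#'
#' Builds the tidy per-experiment table the comparative stage consumes. One
#' row per perfusion experiment (animal) per surface, with the averaged
#' parameters as columns `P1`..`P8`.
#'
#' @param strain_id strain label (gene symbol for modified strains,
#'   `"WT_<db>"` style labels for wild-types).
#' @param database_id wild-type dataset id pairing modified strains to their
#'   controls.
#' @param genotype_class `"modified"` or `"wildtype"`.
#' @param surface microspot `"M1"`/`"M2"`/`"M3"`.
#' @param shear_rate_per_s wall shear rate, 1000 or 1700.
#' @param parameters an [image_parameters()] (averaged over images).
#' @param n_images number of images averaged (target 3).
#' @return one-row data.frame.
#' @export
experiment_record <- function(strain_id, database_id, genotype_class,
                              surface, parameters, shear_rate_per_s = 1000,
                              n_images = 3L) {
  genotype_class <- match.arg(genotype_class, c("modified", "wildtype"))
  if (!shear_rate_per_s %in% c(1000, 1700))
    stop("shear rate must be 1000 or 1700 s^-1", call. = FALSE)
  if (n_images < 1) stop("n_images must be >= 1", call. = FALSE)
  stopifnot(inherits(parameters, "image_parameters"), surface == parameters$surface)
  data.frame(strain_id = strain_id, database_id = database_id,
             genotype_class = genotype_class, surface = surface,
             shear_rate_per_s = shear_rate_per_s, n_images = as.integer(n_images),
             as.list(parameters$values), stringsAsFactors = FALSE)
}

#' Summarize experiments of one strain on one surface
#'
#' Per-parameter mean, sample SD (n-1 denominator) and n over the
#' experiments (animals) of a single strain/surface group. The assay's
#' inclusion rule requires images from at least 3 animals for a modified
#' group and at least 4 for a wild-type group; with `enforce_inclusion`
#' enabled, groups failing the rule raise an exclusion error naming the
#' strain.
#'
#' @param records data.frame of experiment rows (see [experiment_record()])
#'   sharing `strain_id` and `surface`.
#' @param enforce_inclusion apply the minimum-n inclusion rule.
#' @return object of class `strain_summary`: a data.frame with one row per
#'   parameter (`parameter`, `mean`, `sd`, `n`) and strain metadata in
#'   attributes.
#' @export
summarize_strain <- function(records, enforce_inclusion = TRUE) {
  if (is.null(records) || nrow(records) == 0)
    stop("invalid input: zero experiment records", call. = FALSE)
  if (length(unique(records$strain_id)) != 1 || length(unique(records$surface)) != 1)
    stop("records must share one strain and one surface", call. = FALSE)
  cls <- unique(records$genotype_class)
  n_exp <- nrow(records)
  if (enforce_inclusion) {
    need <- if (identical(cls, "wildtype")) 4L else 3L
    if (n_exp < need)
      stop(sprintf("exclusion: strain %s has n = %d experiments (< %d required for %s)",
                   records$strain_id[1], n_exp, need, cls), call. = FALSE)
  }
  pn <- parameter_names()
  stats <- data.frame(parameter = pn,
                      mean = vapply(pn, function(p) mean(records[[p]], na.rm = TRUE), 0),
                      sd = vapply(pn, function(p) stats::sd(records[[p]], na.rm = TRUE), 0),
                      n = vapply(pn, function(p) sum(!is.na(records[[p]])), 0L),
                      row.names = NULL, stringsAsFactors = FALSE)
  stats$mean[stats$n == 0] <- NA
  stats$sd[stats$n < 2] <- NA
  structure(stats, class = c("strain_summary", "data.frame"),
            strain_id = records$strain_id[1], surface = records$surface[1],
            database_id = records$database_id[1], genotype_class = cls,
            n_experiments = n_exp)
}

#' Summarize every strain/surface group of an experiment table
#'
#' @param experiments tidy experiment data.frame (rows as produced by
#'   [experiment_record()] or [generate_strain_table()]).
#' @inheritParams summarize_strain
#' @return long data.frame: `strain_id`, `database_id`, `genotype_class`,
#'   `surface`, `parameter`, `mean`, `sd`, `n`, `n_experiments`.
#' @export
summarize_strains <- function(experiments, enforce_inclusion = TRUE) {
  key <- interaction(experiments$strain_id, experiments$surface, drop = TRUE)
  out <- lapply(split(experiments, key), function(rec) {
    s <- summarize_strain(rec, enforce_inclusion = enforce_inclusion)
    data.frame(strain_id = attr(s, "strain_id"),
               database_id = attr(s, "database_id"),
               genotype_class = attr(s, "genotype_class"),
               surface = attr(s, "surface"),
               s, n_experiments = attr(s, "n_experiments"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Thrombus signature from scaled parameters
#'
#' The thrombus signature summarises thrombus buildup as the sum of the
#' scaled (0-10) aggregate coverage, morphology, multilayer and contraction
#' parameters (P2-P5), range 0-40. If any of the four is missing the
#' signature is undefined (`NA`), never silently zero. The normalised mean
#' (sum / 4) is exposed as an attribute for convenience; the sum is the
#' canonical value.
#'
#' @param scaled named numeric vector of scaled parameters containing
#'   `P2`..`P5` (each 0-10).
#' @return the signature sum (0-40), `NA` if undefined, with attribute
#'   `normalized` = sum / 4.
#' @examples
#' thrombus_signature(c(P2 = 4, P3 = 5, P4 = 6, P5 = 5))  # 20
#' @export
thrombus_signature <- function(scaled) {
  need <- c("P2", "P3", "P4", "P5")
  v <- scaled[need]
  if (length(v) != 4 || any(is.na(v))) {
    out <- NA_real_
    attr(out, "normalized") <- NA_real_
    return(out)
  }
  if (any(v < 0 | v > 10)) stop("scaled parameters must lie in [0, 10]", call. = FALSE)
  out <- sum(v)
  attr(out, "normalized") <- out / 4
  out
}
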