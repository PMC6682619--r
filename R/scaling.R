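#' Univariate 0-10 scaling of one parameter column
#'
#' Strain means of one parameter (on one surface) are linearly mapped to the
#' common 0-10 axis used for heatmap comparison: the observed maximum maps to
#' 10 and zero maps to 0 (all parameters are non-negative and their reported
#' ranges start at zero, so the lower anchor is 0, not the observed minimum).
#' Anchors are returned so that new data can be scaled consistently.
#'
#' @param values non-negative per-strain means; `NA` allowed (stays `NA`).
#' @param anchor_max optional fixed upper anchor; default = observed max.
#' @return list with `scaled` (same length as `values`) and `anchors`
#'   (`c(min = 0, max = ...)`).
#' @examples
#' scale_univariate(c(2, 4, 8))$scaled    # 2.5 5 10
#' @export
scale_univariate <- function(values, anchor_max = NULL) {
  if (all(is.na(values))) stop("invalid input: no non-missing values", call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("invalid input: negative parameter values cannot be scaled", call. = FALSE)
  mx <- if (is.null(anchor_max)) max(values, na.rm = TRUE) else anchor_max
  if (mx == 0) {
    warning("degenerate column: all values are 0; scaled values set to 0")
    scaled <- ifelse(is.na(values), NA_real_, 0)
  } else {
    scaled <- 10 * values / mx
  }
  list(scaled = scaled, anchors = c(min = 0, max = mx))
}

#' Scale a strain summary onto the common 0-10 axis
#'
#' Builds the scaled matrix underlying the comparison heatmaps: rows are
#' strains, columns are (surface, parameter) pairs named `"M1.P1"` etc.
#' Anchors are computed jointly across all wild-type and modified strains in
#' the run (each column's observed maximum mean maps to 10), unless fixed
#' anchors are supplied. Group SDs are carried along on the same scale.
#'
#' @param summary long summary data.frame from [summarize_strains()].
#' @param anchors optional named vector of per-column upper anchors from a
#'   previous run.
#' @return object of class `scaled_matrix`: list with matrices `values`,
#'   `sd`, `n` (strains x columns), the `anchors`, and `meta`
#'   (strain_id, database_id, genotype_class).
#' @export
scale_strain_means <- function(summary, anchors = NULL) {
  cols <- sort(unique(paste(summary$surface, summary$parameter, sep = ".")))
  strains <- unique(summary$strain_id)
  mk <- function() matrix(NA_real_, length(strains), length(cols),
                          dimnames = list(strains, cols))
  vals <- mk(); sds <- mk(); ns <- mk()
  idx <- cbind(match(summary$strain_id, strains),
               match(paste(summary$surface, summary$parameter, sep = "."), cols))
  vals[idx] <- summary$mean; sds[idx] <- summary$sd; ns[idx] <- summary$n
  keep <- colSums(!is.na(vals)) > 0
  vals <- vals[, keep, drop = FALSE]; sds <- sds[, keep, drop = FALSE]
  ns <- ns[, keep, drop = FALSE]
  anch <- numeric(ncol(vals)); names(anch) <- colnames(vals)
  for (j in seq_len(ncol(vals))) {
    a <- if (!is.null(anchors)) anchors[[colnames(vals)[j]]] else NULL
    sc <- scale_univariate(vals[, j], anchor_max = a)
    anch[j] <- sc$anchors[["max"]]
    fac <- if (anch[j] > 0) 10 / anch[j] else 0
    vals[, j] <- sc$scaled
    sds[, j] <- sds[, j] * fac
  }
  meta <- unique(summary[, c("strain_id", "database_id", "genotype_class")])
  rownames(meta) <- meta$strain_id
  structure(list(values = vals, sd = sds, n = ns, anchors = anch,
                 meta = meta[strains, , drop = FALSE]),
            class = "scaled_matrix")
}

#' @export
print.scaled_matrix <- function(x, ...) {
  cat(sprintf("<scaled_matrix> %d strains x %d (surface, parameter) columns\n",
              nrow(x$values), ncol(x$values)))
  cat("  anchors (map to 10):", paste(sprintf("%s=%.3g", names(x$anchors), x$anchors),
                                      collapse = ", "), "\n")
  invisible(x)
}

#' Scaled wild-type subtraction with relevance filter (one strain pair)
#'
#' Subtracts the scaled wild-type means from the scaled modified-strain means
#' and flags which differences are relevant: a cell is relevant iff
#' |delta| exceeds the composite SD of the two groups on the scaled axis.
#' The composite SD is the root-mean-square of the two group SDs by default
#' (`sqrt((sd_mod^2 + sd_wt^2)/2)`); `composite = "max"` uses the more
#' conservative `max(sd_mod, sd_wt)`. Cells failing the filter are reported
#' as unchanged (delta kept, flag `FALSE`).
#'
#' @param modified,wildtype [summarize_strain()] results for the modified
#'   strain and its paired wild-type (same `database_id`, same surface).
#' @param anchors named anchor vector (`"<surface>.<parameter>"` -> max) as
#'   produced by [scale_strain_means()].
#' @param composite `"rms"` or `"max"`.
#' @return data.frame: `parameter`, `delta`, `composite_sd`, `relevant`.
#' @export
delta_heatmap <- function(modified, wildtype, anchors,
                          composite = c("rms", "max")) {
  composite <- match.arg(composite)
  stopifnot(inherits(modified, "strain_summary"), inherits(wildtype, "strain_summary"))
  if (!identical(attr(modified, "database_id"), attr(wildtype, "database_id")))
    stop("pairing error: database ids differ (",
         attr(modified, "database_id"), " vs ", attr(wildtype, "database_id"), ")",
         call. = FALSE)
  if (!identical(attr(modified, "surface"), attr(wildtype, "surface")))
    stop("pairing error: surfaces differ", call. = FALSE)
  surf <- attr(modified, "surface")
  key <- paste(surf, modified$parameter, sep = ".")
  a <- anchors[key]
  fac <- ifelse(is.na(a) | a == 0, NA_real_, 10 / a)
  d <- (modified$mean - wildtype$mean) * fac
  csd <- combine_sd(modified$sd * fac, wildtype$sd * fac, composite)
  data.frame(parameter = modified$parameter, delta = d, composite_sd = csd,
             relevant = !is.na(d) & !is.na(csd) & abs(d) > csd,
             row.names = NULL, stringsAsFactors = FALSE)
}

combine_sd <- function(s1, s2, composite) {
  if (composite == "rms") sqrt((s1^2 + s2^2) / 2) else pmax(s1, s2)
}

#' Wild-type subtraction heatmap for all modified strains
#'
#' Applies the scaled subtraction and relevance filter of [delta_heatmap()]
#' to every modified strain in a [scale_strain_means()] result, pairing each
#' strain with the wild-type sharing its database id.
#'
#' @param scaled a `scaled_matrix`.
#' @param composite composite-SD rule, see [delta_heatmap()].
#' @return object of class `delta_matrix`: matrices `delta`, `composite_sd`,
#'   `relevant` (modified strains x columns), the `anchors`, the pairing
#'   `meta`, and `filtered` (delta with irrelevant cells set to 0 -
#'   "unchanged" - for display and downstream summation).
#' @export
build_delta_matrix <- function(scaled, composite = c("rms", "max")) {
  composite <- match.arg(composite)
  stopifnot(inherits(scaled, "scaled_matrix"))
  meta <- scaled$meta
  mod <- meta$strain_id[meta$genotype_class == "modified"]
  wts <- meta[meta$genotype_class == "wildtype", ]
  if (nrow(wts) == 0) stop("no wild-type strains in the scaled matrix", call. = FALSE)
  wt_of <- function(db) {
    w <- wts$strain_id[wts$database_id == db]
    if (length(w) != 1)
      stop("pairing error: database id ", db, " matches ", length(w),
           " wild-type strains", call. = FALSE)
    w
  }
  cols <- colnames(scaled$values)
  d <- matrix(NA_real_, length(mod), length(cols), dimnames = list(mod, cols))
  csd <- d
  for (s in mod) {
    w <- wt_of(meta[s, "database_id"])
    d[s, ] <- scaled$values[s, ] - scaled$values[w, ]
    csd[s, ] <- combine_sd(scaled$sd[s, ], scaled$sd[w, ], composite)
  }
  rel <- !is.na(d) & !is.na(csd) & abs(d) > csd
  filt <- ifelse(rel, d, ifelse(is.na(d), NA_real_, 0))
  structure(list(delta = d, composite_sd = csd, relevant = rel,
                 filtered = filt, anchors = scaled$anchors,
                 meta = meta, composite = composite),
            class = "delta_matrix")
}

#' @export
print.delta_matrix <- function(x, ...) {
  cat(sprintf("<delta_matrix> %d modified strains x %d columns; %d/%d cells relevant\n",
              nrow(x$delta), ncol(x$delta), sum(x$relevant, na.rm = TRUE),
              sum(!is.na(x$delta))))
  invisible(x)
}

#' Per-strain summed effect across parameters
#'
#' Sums relevance-filtered deltas over a set of parameters on one surface.
#' Used for the thrombus-signature ranking (P2-P5), the adhesion ranking
#' (P1), and the overall P1-P5 effect compared against in vivo phenotypes.
#' Irrelevant cells contribute 0 (they are "unchanged").
#'
#' @param dm a [build_delta_matrix()] result.
#' @param parameters parameter subset to sum.
#' @param surface microspot whose columns are summed.
#' @param filtered use relevance-filtered deltas (default) or raw deltas.
#' @return named numeric vector, one value per modified strain.
#' @export
effect_sum <- function(dm, parameters = c("P2", "P3", "P4", "P5"),
                       surface = "M1", filtered = TRUE) {
  stopifnot(inherits(dm, "delta_matrix"))
  cols <- intersect(paste(surface, parameters, sep = "."), colnames(dm$delta))
  if (length(cols) == 0) stop("no matching columns on surface ", surface, call. = FALSE)
  m <- if (filtered) dm$filtered else dm$delta
  rowSums(m[, cols, drop = FALSE], na.rm = TRUE)
}
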