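#' Order heatmap rows by effect ranking or hierarchical clustering
#'
#' Rows of a subtraction heatmap can be arranged by the strain's effect on
#' the thrombus signature (summed relevance-filtered P2-P5 deltas), on
#' platelet adhesion (P1 delta), or by unsupervised agglomerative
#' hierarchical clustering (Euclidean distance, complete linkage, missing
#' cells pairwise-excluded), returning the dendrogram leaf order.
#' Effect rankings are ascending (strongest suppression first) with ties
#' broken alphabetically by strain id for determinism.
#'
#' @param x a [build_delta_matrix()] result or a plain numeric matrix with
#'   strain row names and `"<surface>.<parameter>"` column names.
#' @param rank_by `"signature"`, `"adhesion"`, or `"none"` (clustering).
#' @param surface microspot used for the effect rankings.
#' @return list with `rows` (ordered strain ids), `values` (the ranking
#'   values, or merge heights for clustering), and `method`.
#' @export
rank_and_cluster <- function(x, rank_by = c("signature", "adhesion", "none"),
                             surface = "M1") {
  rank_by <- match.arg(rank_by)
  m <- if (inherits(x, "delta_matrix")) x$filtered else x
  if (is.null(dim(m)) || nrow(m) == 0) stop("empty matrix", call. = FALSE)

  if (rank_by == "none") {
    if (nrow(m) < 3) {
      ord <- order(rownames(m))
      return(list(rows = rownames(m)[ord], values = NULL, method = "hclust"))
    }
    d <- stats::dist(m, method = "euclidean")
    d[is.na(d)] <- max(d, na.rm = TRUE) + 1  # fully-missing pairs pushed apart
    hc <- stats::hclust(d, method = "complete")
    return(list(rows = rownames(m)[hc$order], values = hc$height,
                method = "hclust", hclust = hc))
  }

  vals <- if (rank_by == "signature") {
    if (inherits(x, "delta_matrix")) effect_sum(x, c("P2", "P3", "P4", "P5"), surface)
    else rowSums(m[, paste(surface, c("P2", "P3", "P4", "P5"), sep = "."),
                   drop = FALSE], na.rm = TRUE)
  } else {
    col <- paste(surface, "P1", sep = ".")
    if (!col %in% colnames(m)) stop("no ", col, " column", call. = FALSE)
    m[, col]
  }
  ord <- order(vals, rownames(m))
  list(rows = rownames(m)[ord], values = vals[ord], method = rank_by)
}
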