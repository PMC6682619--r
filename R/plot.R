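#' Render a subtraction heatmap
#'
#' Draws the relevance-filtered delta matrix with the assay's conventional
#' diverging palette: green for decreased, black for unchanged (or
#' sub-threshold), red for increased parameters. Rows are ordered by the
#' requested ranking.
#'
#' @param x a [build_delta_matrix()] result.
#' @param rank_by row ordering passed to [rank_and_cluster()].
#' @param surface microspot used for the ranking.
#' @param zlim symmetric color range; defaults to the largest |delta|.
#' @param ... ignored.
#' @return invisibly, the ordered matrix that was drawn.
#' @export
plot.delta_matrix <- function(x, rank_by = "signature", surface = "M1",
                              zlim = NULL, ...) {
  ord <- rank_and_cluster(x, rank_by, surface = surface)$rows
  m <- x$filtered[ord, , drop = FALSE]
  if (is.null(zlim)) zlim <- max(abs(m), na.rm = TRUE)
  if (zlim == 0) zlim <- 1
  pal <- grDevices::colorRampPalette(c("#00c800", "#004000", "black",
                                       "#400000", "#c80000"))(101)
  op <- graphics::par(mar = c(5, 6, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)),
                  t(pmin(pmax(m[rev(seq_len(nrow(m))), , drop = FALSE],
                              -zlim), zlim)),
                  zlim = c(-zlim, zlim), col = pal, axes = FALSE,
                  xlab = "", ylab = "")
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(nrow(m)), rev(rownames(m)), las = 2,
                 cex.axis = 0.8)
  graphics::box()
  invisible(m)
}
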