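#' Heatmap of normalized individual circadian patterns
#'
#' One horizontal strip per ego, hours 0-23 on the x axis, brighter colours
#' for higher (unity-normalized) call ratios.
#'
#' @param patterns matrix from [hourly_patterns()] (rows = egos).
#' @param normalize unity-normalize each row first (default `TRUE`).
#' @param ... passed to [graphics::image()].
#' @return Invisibly, the matrix drawn.
#' @export
plot_rhythm_heatmap <- function(patterns, normalize = TRUE, ...) {
  x <- patterns
  if (normalize) x <- t(apply(x, 1L, unity_normalize))
  graphics::image(x = 0:23, y = seq_len(nrow(x)), z = t(x)[, rev(seq_len(nrow(x))), drop = FALSE],
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "hour of day", ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(nrow(x)), labels = rev(rownames(patterns)),
                 las = 2, cex.axis = 0.6)
  invisible(x)
}

#' Bar plot of the population-average circadian pattern
#'
#' Bars give the ego-averaged hourly call fraction; whiskers give the
#' between-ego standard deviation.
#'
#' @param agg result of [aggregate_pattern()].
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot_aggregate_pattern <- function(agg, ...) {
  mid <- graphics::barplot(agg$mean, names.arg = 0:23,
                           xlab = "hour of day",
                           ylab = "mean call fraction", ...)
  graphics::arrows(mid, pmax(agg$mean - agg$sd, 0), mid,
                   agg$mean + agg$sd, angle = 90, code = 3, length = 0.02)
  invisible(mid)
}
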