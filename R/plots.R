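#' Scatter plot of the screen plane
#'
#' Plots differential H3K27me3 modification against differential expression
#' for all TFs, highlights known factors, and draws the signature box when
#' thresholds are available. Requires ggplot2.
#'
#' @param result A `screen_result` from [run_screen()].
#' @return A ggplot object.
#' @export
plot_screen <- function(result) {
  stopifnot(inherits(result, "screen_result"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_screen requires the ggplot2 package")
  thr <- attr(result, "thresholds")
  p <- ggplot2::ggplot(result,
                       ggplot2::aes(x = .data$dz_expr, y = .data$dz_mod)) +
    ggplot2::geom_point(colour = "grey60", size = 0.8) +
    ggplot2::geom_point(data = result[result$known, , drop = FALSE],
                        colour = "blue", size = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "differential expression (dZ, target - source)",
                  y = "differential H3K27me3 (dZ, target - source)") +
    ggplot2::theme_classic()
  if (all(is.finite(thr))) {
    lims <- data.frame(
      xmin = thr[["dz_expr_min"]], xmax = max(result$dz_expr),
      ymin = min(result$dz_mod), ymax = thr[["dz_mod_max"]]
    )
    p <- p + ggplot2::geom_rect(
      data = lims,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax),
      inherit.aes = FALSE, fill = NA, colour = "black",
      linetype = 2
    )
  }
  p
}
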