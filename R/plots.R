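#' Plot a per-SNP association track
#'
#' Manhattan-style plot of `-ln(p)` against position, faceted by
#' chromosome.
#'
#' @param track A `gps_pvalues` tibble from [test_track()].
#' @param alpha Optional significance threshold drawn as a horizontal line
#'   at `-ln(alpha)`.
#' @return A ggplot object.
#' @export
plot_pvalue_track <- function(track, alpha = NULL) {
  p <- ggplot2::ggplot(track,
                       ggplot2::aes(x = .data$pos / 1e6, y = .data$neg_ln_p)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "-ln(p)") +
    ggplot2::theme_minimal()
  if (!is.null(alpha)) {
    p <- p + ggplot2::geom_hline(yintercept = -log(alpha),
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Plot a per-window significant-SNP ratio track
#'
#' The noise-reduced view of a scan: one point per scored window at the
#' window midpoint, ratio on the y axis.
#'
#' @param ratios A `gps_ratios` tibble from [window_ratio()].
#' @param intervals Optional `gps_intervals` to highlight.
#' @return A ggplot object.
#' @export
plot_ratio_track <- function(ratios, intervals = NULL) {
  r <- dplyr::filter(ratios, !.data$skipped)
  p <- ggplot2::ggplot(r, ggplot2::aes(x = .data$midpoint / 1e6,
                                       y = .data$ratio)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "Window midpoint (Mb)", y = "Significant-SNP ratio") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(intervals) && nrow(intervals)) {
    p <- p + ggplot2::geom_rect(
      data = tibble::as_tibble(intervals),
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, fill = "red", alpha = 0.15,
      inherit.aes = FALSE
    )
  }
  p
}

#' @method autoplot gps_pvalues
#' @export
autoplot.gps_pvalues <- function(object, ...) plot_pvalue_track(object, ...)

#' @method autoplot gps_ratios
#' @export
autoplot.gps_ratios <- function(object, ...) plot_ratio_track(object, ...)

#' @method autoplot gps_scan
#' @export
autoplot.gps_scan <- function(object, ...) {
  plot_ratio_track(object$ratios, object$intervals)
}
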