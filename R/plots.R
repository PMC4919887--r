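#' Plot an MSD histogram
#'
#' Log-axis bar plot of the per-window mean single-frame MSD with the
#' population split threshold, if any, marked.
#'
#' @param h an [msd_histogram()] object.
#' @return a ggplot object.
#' @export
plot_msd_histogram <- function(h) {
  df <- data.frame(mid = h$mids, count = h$counts)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = 1 / h$bins_per_decade * 0.92,
                      fill = "grey35") +
    ggplot2::labs(x = expression(log[10] ~ bar(R[tau]^2) ~ (mu * m^2)),
                  y = "windows") +
    ggplot2::theme_classic()
  if (!is.na(h$threshold))
    p <- p + ggplot2::geom_vline(xintercept = log10(h$threshold),
                                 linetype = 2, colour = "red3")
  p
}

#' Plot an (MSD, V) contour map
#'
#' Filled-contour rendering of the smoothed density on log-log axes, with
#' the free-diffusion level V = 2 marked; optionally overlays detected
#' peaks.
#'
#' @param map a [contour_map()] object.
#' @param peaks optional tibble from [find_peaks()].
#' @return a ggplot object.
#' @export
plot_contour_map <- function(map, peaks = NULL) {
  df <- expand.grid(x = map$x, y = map$y)
  df$z <- as.vector(map$z)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        z = .data$z)) +
    ggplot2::geom_contour_filled(bins = 10, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = log10(2), linetype = 3,
                        colour = "white") +
    ggplot2::labs(x = expression(log[10] ~ bar(R[tau]^2) ~ (mu * m^2)),
                  y = expression(log[10] ~ V(bar(R[tau]^2)))) +
    ggplot2::theme_classic()
  if (!is.null(peaks) && nrow(peaks) > 0)
    p <- p + ggplot2::annotate("point", x = log10(peaks$mean_R2),
                               y = log10(peaks$V), shape = 4,
                               colour = "red", size = 3)
  p
}
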