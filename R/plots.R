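#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a double-plotted actogram
#'
#' The standard chronobiology raster: one row per day, 48 h per row with
#' the next day re-plotted on the right half, singing as tile darkness.
#'
#' @param object An `actogram` from [build_actogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot actogram
#' @export
autoplot.actogram <- function(object, ...) {
  m <- unclass(object)
  df <- tibble(
    day = rep(seq_len(nrow(m)) - 1L, times = ncol(m)),
    hour = rep((seq_len(ncol(m)) - 0.5) / 60, each = nrow(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$day,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_x_continuous(breaks = seq(0, 48, 12),
                                expand = c(0, 0)) +
    ggplot2::scale_fill_gradient(low = "white", high = "grey10",
                                 na.value = "grey80", limits = c(0, 1)) +
    ggplot2::labs(x = "Time (h, double-plotted)", y = "Day",
                  fill = "Singing") +
    ggplot2::theme_minimal()
}

#' Plot a Lomb-Scargle periodogram
#'
#' Power against candidate period with the alpha-level significance
#' threshold as a dashed line.
#'
#' @param object An `ls_periodogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ls_periodogram
#' @export
autoplot.ls_periodogram <- function(object, ...) {
  ggplot2::ggplot(object$spectrum,
                  ggplot2::aes(x = .data$period_h, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "Period (h)", y = "Normalized LS power") +
    ggplot2::theme_minimal()
}

#' Polar plot of a wrapped activity profile
#'
#' @param profile A [polar_profile()] tibble.
#' @param bin_min Bin width used (for bar width).
#' @return A ggplot in polar coordinates (ZT0 at the top, clockwise).
#' @export
plot_polar_profile <- function(profile, bin_min = 30) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$zt + bin_min / 120,
                                        y = .data$value)) +
    ggplot2::geom_col(width = bin_min / 60, fill = "purple", alpha = 0.7) +
    ggplot2::coord_polar(start = 0) +
    ggplot2::scale_x_continuous(limits = c(0, 24), breaks = seq(0, 18, 6)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Zeitgeber time (h)", y = "Mean singing") +
    ggplot2::theme_minimal()
}
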