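#' Plot a channel layout
#'
#' Top-view sensor map with interhemispheric pairs connected and the pair
#' of interest highlighted.
#'
#' @param object a `channel_layout`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.channel_layout <- function(object, ...) {
  ch <- tidy(object)
  segs <- tibble::tibble(
    x = ch$x[object$pairs$left], y = ch$y[object$pairs$left],
    xend = ch$x[object$pairs$right], yend = ch$y[object$pairs$right],
    poi = object$pairs$pair == object$pair_of_interest
  )
  ggplot2::ggplot(ch, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(xend = .data$xend, yend = .data$yend,
                                       color = .data$poi),
                          show.legend = FALSE) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$hemisphere), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$name), vjust = -1, size = 2.8) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey70", `TRUE` = "red")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, shape = NULL,
                  title = "Sensor layout (pair of interest in red)") +
    ggplot2::theme_minimal()
}

#' Plot a spectral estimate
#'
#' Power spectra per channel on a log scale, with the regime boundary
#' marked.
#'
#' @param object a `spectral_estimate`.
#' @param channels channel names to show (default: up to 6).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.spectral_estimate <- function(object, channels = NULL, ...) {
  df <- tidy(object)
  if (is.null(channels)) channels <- utils::head(unique(df$channel), 6)
  df <- df[df$channel %in% channels, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$power,
                                   color = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::geom_vline(xintercept = 35.5, linetype = "dashed",
                        color = "grey50") +
    ggplot2::labs(x = "frequency (Hz)", y = expression(power ~ (mu * V^2 / Hz)),
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot band connectivity
#'
#' Pair-by-band coherence (or PLV) values; the pair of interest can be
#' highlighted via the layout.
#'
#' @param conn a `band_connectivity` tibble.
#' @param value column to plot (default `"coherence"`).
#' @return a ggplot.
#' @export
plot_band_connectivity <- function(conn, value = "coherence") {
  stopifnot(value %in% names(conn))
  ggplot2::ggplot(conn, ggplot2::aes(x = .data$band,
                                     y = .data[[value]],
                                     group = .data$pair)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_minimal()
}

#' Plot an entropy map
#'
#' Channel-by-band tile map of Shannon spectral entropy.
#'
#' @param em an `entropy_map` tibble.
#' @return a ggplot.
#' @export
plot_entropy_map <- function(em) {
  ggplot2::ggplot(em, ggplot2::aes(x = .data$band, y = .data$channel,
                                   fill = .data$entropy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "H (nats)") +
    ggplot2::theme_minimal()
}
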