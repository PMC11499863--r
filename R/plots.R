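#' Plot a modulation spectrum
#'
#' Heatmap of per-channel modulation power (cochlear center frequency
#' against modulation frequency) with the broadband (channel-summed)
#' profile available via `plot_broadband()`.
#'
#' @param object a [modulation_spectrum()] or [modspec_difference()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.modulation_spectrum <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$mod_hz, .data$center_hz, fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "modulation frequency (Hz)", y = "cochlear channel (Hz)",
                  fill = "power")
}

#' @rdname autoplot.modulation_spectrum
#' @export
autoplot.modspec_difference <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$mod_hz, .data$center_hz, fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "modulation frequency (Hz)", y = "cochlear channel (Hz)",
                  fill = expression(Delta * "power"))
}

#' Broadband modulation profile
#'
#' @param ms a [modulation_spectrum()] or [modspec_difference()].
#' @return a ggplot of channel-summed power over modulation frequency.
#' @export
plot_broadband <- function(ms) {
  tibble(mod_hz = ms$mod_freqs, power = ms$broadband) |>
    ggplot2::ggplot(ggplot2::aes(.data$mod_hz, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "modulation frequency (Hz)", y = "broadband power")
}

#' Plot a PLV spectrum
#'
#' Channel-averaged stimulus-brain PLV over frequency, with per-channel
#' traces in the background.
#'
#' @param object a [plv_spectrum()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.plv_spectrum <- function(object, ...) {
  long <- tidy(object)
  avg <- long |>
    dplyr::group_by(.data$freq_hz) |>
    dplyr::summarise(plv = mean(.data$plv), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$freq_hz, .data$plv)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$channel), alpha = 0.25) +
    ggplot2::geom_line(data = avg, linewidth = 1) +
    ggplot2::labs(x = "frequency (Hz)", y = "PLV")
}

#' Plot early-vs-late PLV change per channel
#'
#' @param object an [early_late_change()] tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.plv_change <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$channel, .data$delta_plv,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = expression(Delta * "PLV (late - early)"),
                  fill = "FDR-significant")
}

#' Plot condition-by-block d-prime differences
#'
#' Group means of the d' difference relative to the no-modulation baseline
#' with within-subject (Cousineau-Morey) error bars.
#'
#' @param ddprime a [condition_block_summary()] tibble.
#' @return a ggplot.
#' @export
plot_ddprime <- function(ddprime) {
  condition_means(ddprime) |>
    ggplot2::ggplot(ggplot2::aes(factor(.data$block), .data$mean,
                                 group = .data$condition, colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem_ws,
                                          ymax = .data$mean + .data$sem_ws)) +
    ggplot2::labs(x = "block", y = expression(Delta * "d'"), colour = "condition")
}
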