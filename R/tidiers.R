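#' Tidy a modulation spectrum into long format
#'
#' @param x a [modulation_spectrum()] or [modspec_difference()].
#' @param ... unused.
#' @return tibble: `channel`, `center_hz`, `mod_hz`, `power`.
#' @export
tidy.modulation_spectrum <- function(x, ...) {
  tidyr::expand_grid(channel = seq_along(x$center_freqs), mod_hz = x$mod_freqs) |>
    dplyr::mutate(center_hz = x$center_freqs[.data$channel],
                  power = as.vector(t(x$power))) |>
    dplyr::select("channel", "center_hz", "mod_hz", "power")
}

#' @rdname tidy.modulation_spectrum
#' @export
tidy.modspec_difference <- function(x, ...) {
  tidyr::expand_grid(channel = seq_along(x$center_freqs), mod_hz = x$mod_freqs) |>
    dplyr::mutate(center_hz = x$center_freqs[.data$channel],
                  power = as.vector(t(x$difference))) |>
    dplyr::select("channel", "center_hz", "mod_hz", "power")
}

#' Tidy a PLV spectrum into long format
#'
#' @param x a [plv_spectrum()].
#' @param ... unused.
#' @return tibble: `channel`, `freq_hz`, `plv`, `segment`.
#' @export
tidy.plv_spectrum <- function(x, ...) {
  tidyr::expand_grid(channel = x$channel_labels, freq_hz = x$freqs) |>
    dplyr::mutate(plv = as.vector(t(x$plv)), segment = x$segment_tag)
}

#' Tidy / summarize an interaction-contrast fit
#'
#' `tidy()` returns the slope term with its permutation p-value; `glance()`
#' returns one row of fit metadata.
#'
#' @param x an [interaction_contrast()] result.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.am_contrast <- function(x, ...) {
  tibble(term = "asrs_slope", estimate = x$estimate, p.value = x$p_value)
}

#' @rdname tidy.am_contrast
#' @export
glance.am_contrast <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, n_perm = x$n_perm,
         p.value = x$p_value, method = x$method)
}

#' Tidy a stimulus-validation report
#'
#' @param x a [validate_stimulus()] result.
#' @param ... unused.
#' @return one-row tibble of check outcomes.
#' @export
tidy.stimulus_validation <- function(x, ...) {
  tibble(
    max_spectrum_dev_db = x$max_spectrum_dev_db,
    peak_rate_hz = x$peak_rate,
    out_of_band_fraction = x$out_of_band_fraction,
    spectrum_passed = x$spectrum_passed,
    band_passed = x$band_passed,
    passed = x$passed
  )
}
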