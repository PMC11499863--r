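#' EEG recording container
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param sample_rate sampling rate in Hz.
#' @param channel_labels unique 10-20-system channel names.
#' @param events optional sample indices of trial onsets.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sample_rate, channel_labels = NULL, events = integer(0)) {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric matrix (channels x samples)", class = "ammod_invalid_input")
  }
  if (anyNA(data)) abort("EEG contains NAs", class = "ammod_invalid_input")
  if (is.null(channel_labels)) channel_labels <- paste0("Ch", seq_len(nrow(data)))
  if (anyDuplicated(channel_labels)) {
    abort("channel labels must be unique", class = "ammod_invalid_input")
  }
  stopifnot(length(channel_labels) == nrow(data), sample_rate > 0)
  structure(
    list(data = data, sample_rate = sample_rate,
         channel_labels = channel_labels, events = as.integer(events)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %.1f s @ %g Hz\n",
              nrow(x$data), ncol(x$data) / x$sample_rate, x$sample_rate))
  invisible(x)
}

#' Write / read an EEG recording as TSV + JSON sidecar
#'
#' The TSV holds samples in rows and channels in columns (header = labels);
#' the sidecar `<path>.json` records `sample_rate`, `channel_labels` and
#' `events`.
#'
#' @param rec an [eeg_recording()]; `path` the TSV path.
#' @return `path` invisibly / an `eeg_recording`.
#' @export
write_eeg_matrix <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  m <- t(rec$data)
  colnames(m) <- rec$channel_labels
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(sample_rate = rec$sample_rate, channel_labels = rec$channel_labels,
         events = rec$events),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_eeg_matrix
#' @export
read_eeg_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  eeg_recording(t(unname(m)), meta$sample_rate, meta$channel_labels,
                meta$events %||% integer(0))
}

#' Broadband stimulus envelope for coupling analysis
#'
#' EEG and audio live at very different sampling rates, and filtering raw
#' audio at 1-50 Hz would capture near-DC pressure rather than perceptual
#' modulation. The stimulus signal used for phase-locking is therefore the
#' broadband cochlear envelope (channel sum of the cochleagram), lowpassed
#' below the target Nyquist and resampled to the EEG rate.
#'
#' @param track an [audio_track()].
#' @param target_rate EEG sampling rate in Hz.
#' @param ... passed to [cochlear_filterbank()].
#' @return numeric envelope sampled at `target_rate`.
#' @export
stimulus_envelope_for_plv <- function(track, target_rate, ...) {
  stopifnot(inherits(track, "audio_track"))
  if (max(abs(track$samples)) == 0) {
    abort("silent stimulus has no envelope", class = "ammod_invalid_input")
  }
  coch <- cochlear_filterbank(track, ...)
  if (target_rate > coch$frame_rate) {
    abort("`target_rate` above the envelope frame rate", class = "ammod_invalid_parameter")
  }
  env <- colSums(coch$envelopes)
  # guard aliasing before resampling down to the EEG rate
  lp <- signal::butter(4, min(0.4 * target_rate, 0.45 * coch$frame_rate) / (coch$frame_rate / 2))
  env <- signal::filtfilt(lp, env)
  t_old <- seq(0, by = 1 / coch$frame_rate, length.out = length(env))
  n_new <- floor(t_old[length(t_old)] * target_rate) + 1
  t_new <- seq(0, by = 1 / target_rate, length.out = n_new)
  approx(t_old, env, xout = t_new)$y
}

# complex Morlet convolution (FFT-based, same length, centered)
morlet_filter <- function(x, freq, sample_rate, n_cycles = 7) {
  sigma_t <- n_cycles / (2 * pi * freq)
  half <- ceiling(4 * sigma_t * sample_rate)
  tt <- (-half:half) / sample_rate
  ker <- exp(2i * pi * freq * tt) * exp(-tt^2 / (2 * sigma_t^2))
  ker <- ker / sum(Mod(ker))
  n <- length(x)
  nfft <- next_fast_len(n + 2 * half)
  X <- fft(c(x, numeric(nfft - n)))
  K <- fft(c(ker, complex(real = numeric(nfft - length(ker)))))
  y <- fft(X * K, inverse = TRUE) / nfft
  y[(half + 1):(half + n)]
}

#' Instantaneous phase in a narrow band
#'
#' Gaussian-windowed (Morlet) complex bandpass centered at `freq` with
#' `n_cycles` cycles, followed by the analytic-signal phase. Samples within
#' three cycles of either edge are flagged for exclusion from phase-locking
#' estimates.
#'
#' @param x numeric signal.
#' @param freq center frequency in Hz (0 < freq < Nyquist).
#' @param sample_rate sampling rate in Hz.
#' @param n_cycles Morlet width (default 7).
#' @return object of class `phase_series`: `phase` (radians in (-pi, pi\]),
#'   `freq`, `sample_rate`, `edge` (logical exclusion mask).
#' @export
narrowband_phase <- function(x, freq, sample_rate, n_cycles = 7) {
  if (freq <= 0) abort("`freq` must be positive", class = "ammod_invalid_parameter")
  if (freq >= sample_rate / 2) abort("`freq` at or above Nyquist", class = "ammod_invalid_parameter")
  y <- morlet_filter(x, freq, sample_rate, n_cycles)
  n_edge <- min(length(x), ceiling(3 * sample_rate / freq))
  edge <- rep(FALSE, length(x))
  edge[seq_len(n_edge)] <- TRUE
  edge[seq.int(length(x) - n_edge + 1, length(x))] <- TRUE
  structure(
    list(phase = Arg(y), freq = freq, sample_rate = sample_rate, edge = edge),
    class = "phase_series"
  )
}

#' Phase-locking value between two phase series
#'
#' `PLV = |mean(exp(i (phi1 - phi2)))|`, the magnitude of the mean complex
#' phase difference, normalized by the sample count so the value lies in
#' \[0, 1\]: 1 for perfect locking (including any constant offset), near 0
#' for independent phases. Edge-flagged samples of either series are
#' excluded.
#'
#' @param p1,p2 [narrowband_phase()] results at the same frequency, or raw
#'   numeric phase vectors.
#' @return scalar in \[0, 1\].
#' @export
plv <- function(p1, p2) {
  get_phase <- function(p) if (inherits(p, "phase_series")) p$phase else as.numeric(p)
  get_edge <- function(p, n) if (inherits(p, "phase_series")) p$edge else rep(FALSE, n)
  ph1 <- get_phase(p1); ph2 <- get_phase(p2)
  if (length(ph1) != length(ph2)) abort("phase series lengths differ", class = "ammod_invalid_input")
  if (inherits(p1, "phase_series") && inherits(p2, "phase_series") && p1$freq != p2$freq) {
    abort("phase series are at different frequencies", class = "ammod_invalid_input")
  }
  keep <- !(get_edge(p1, length(ph1)) | get_edge(p2, length(ph2)))
  Mod(mean(exp(1i * (ph1[keep] - ph2[keep]))))
}

#' Stimulus-brain PLV spectrum
#'
#' PLV between each EEG channel and the stimulus envelope, at every
#' frequency in `freqs` (default 1-50 Hz in 1-Hz bins), using Morlet
#' filtering of both signals in parallel and excluding filter edges.
#'
#' @param eeg an [eeg_recording()].
#' @param stim numeric stimulus signal at the EEG sampling rate (see
#'   [stimulus_envelope_for_plv()]), same length as the recording.
#' @param freqs frequencies in Hz (default `1:50`).
#' @param n_cycles Morlet width.
#' @param segment_tag `"whole"`, `"early"` or `"late"` provenance label.
#' @return object of class `plv_spectrum`: `plv` (channels x freqs matrix in
#'   \[0,1\]), `freqs`, `channel_labels`, `segment_tag`.
#' @export
plv_spectrum <- function(eeg, stim, freqs = 1:50, n_cycles = 7, segment_tag = "whole") {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (length(stim) != ncol(eeg$data)) {
    abort("stimulus and EEG lengths differ", class = "ammod_invalid_input")
  }
  if (max(freqs) >= eeg$sample_rate / 2) {
    abort("frequencies reach Nyquist", class = "ammod_invalid_parameter")
  }
  nch <- nrow(eeg$data)
  out <- matrix(NA_real_, nch, length(freqs))
  for (j in seq_along(freqs)) {
    sp <- narrowband_phase(stim, freqs[j], eeg$sample_rate, n_cycles)
    for (ch in seq_len(nch)) {
      ep <- narrowband_phase(eeg$data[ch, ], freqs[j], eeg$sample_rate, n_cycles)
      out[ch, j] <- plv(ep, sp)
    }
  }
  structure(
    list(plv = out, freqs = freqs, channel_labels = eeg$channel_labels,
         segment_tag = segment_tag),
    class = "plv_spectrum"
  )
}

#' @export
print.plv_spectrum <- function(x, ...) {
  cat(sprintf("<plv_spectrum> %d channels x %d freqs (%g-%g Hz), segment: %s\n",
              nrow(x$plv), length(x$freqs), min(x$freqs), max(x$freqs), x$segment_tag))
  invisible(x)
}

# montage groups by 10-20 label prefix
channel_group <- function(labels, set = c("all", "frontal", "central", "parietal",
                                          "frontocentral")) {
  set <- match.arg(set)
  pref <- switch(set,
    all = "^(F|C|P|O|T)", frontal = "^(Fp|F)[^C]*$|^F\\d|^Fz$",
    central = "^C", parietal = "^P", frontocentral = "^(F|C)"
  )
  grepl(pref, labels)
}

#' Binned effect size between two PLV spectra
#'
#' Channel-set-averaged PLV is sampled at bin centers (multiples of
#' `bin_width`; a 4-Hz binning over 1-50 Hz captures 8, 12, 16, 20, 24, 28
#' and 32 Hz among its centers) and Cohen's d is computed as the paired
#' effect across bins: `mean(A - B) / sd(A - B)`. When coupling is elevated
#' specifically at multiples of 4 Hz the 4-Hz binning concentrates the
#' difference and yields a larger d than the 1-Hz binning.
#'
#' @param plv_a,plv_b [plv_spectrum()] objects on matching grids.
#' @param bin_widths Hz bin widths to report (default `c(4, 1)`).
#' @param channel_set `"all"`, `"frontal"`, `"central"`, `"parietal"` or
#'   `"frontocentral"` montage group.
#' @return tibble with `bin_width`, `n_bins`, `cohens_d` (Inf with a
#'   diagnostic message when the paired differences have zero variance).
#' @export
binned_effect_size <- function(plv_a, plv_b, bin_widths = c(4, 1),
                               channel_set = "all") {
  stopifnot(inherits(plv_a, "plv_spectrum"), inherits(plv_b, "plv_spectrum"))
  if (!isTRUE(all.equal(plv_a$freqs, plv_b$freqs))) {
    abort("PLV spectra on different frequency grids", class = "ammod_invalid_input")
  }
  sel <- channel_group(plv_a$channel_labels, channel_set)
  if (!any(sel)) sel <- rep(TRUE, length(plv_a$channel_labels))
  a <- colMeans(plv_a$plv[sel, , drop = FALSE])
  b <- colMeans(plv_b$plv[sel, , drop = FALSE])
  purrr::map_dfr(bin_widths, function(bw) {
    centers <- plv_a$freqs[plv_a$freqs %% bw == 0]
    if (length(centers) < 3) abort("fewer than 3 bins", class = "ammod_insufficient_data")
    idx <- match(centers, plv_a$freqs)
    d <- a[idx] - b[idx]
    s <- sd(d)
    if (s < 1e-12 * max(abs(mean(d)), 1)) s <- 0 # numerically constant difference
    cd <- if (s == 0) {
      if (mean(d) == 0) 0 else { message("zero-variance paired differences; Cohen's d infinite"); Inf * sign(mean(d)) }
    } else mean(d) / s
    tibble(bin_width = bw, n_bins = length(centers), cohens_d = cd)
  })
}

#' Early-vs-late change in stimulus-brain coupling
#'
#' The recording is cut into contiguous epochs (default 10 s); PLV at `freq`
#' is computed per epoch per channel; epochs are split into early and late
#' halves by index; each channel gets a two-sample t-test of late vs early
#' epoch PLVs, Benjamini-Hochberg corrected across channels at rate `q`.
#'
#' @param eeg an [eeg_recording()].
#' @param stim stimulus envelope at the EEG rate, same length.
#' @param freq analysis frequency in Hz.
#' @param epoch_s epoch length in seconds (default 10).
#' @param q FDR level (default 0.05).
#' @param n_cycles Morlet width.
#' @return tibble of class `plv_change`: `channel`, `plv_early`, `plv_late`,
#'   `delta_plv`, `t`, `p`, `p_adj`, `significant`.
#' @export
early_late_change <- function(eeg, stim, freq, epoch_s = 10, q = 0.05, n_cycles = 7) {
  stopifnot(inherits(eeg, "eeg_recording"))
  n <- ncol(eeg$data)
  ne <- n %/% round(epoch_s * eeg$sample_rate)
  if (ne < 6) {
    abort("recording too short: need >= 3 epochs per half", class = "ammod_insufficient_data")
  }
  len <- round(epoch_s * eeg$sample_rate)
  sp <- narrowband_phase(stim, freq, eeg$sample_rate, n_cycles)
  half1 <- seq_len(ne %/% 2)
  epoch_idx <- lapply(seq_len(ne), function(e) ((e - 1) * len + 1):(e * len))

  res <- purrr::map_dfr(seq_len(nrow(eeg$data)), function(ch) {
    ep <- narrowband_phase(eeg$data[ch, ], freq, eeg$sample_rate, n_cycles)
    dphi <- exp(1i * (ep$phase - sp$phase))
    keep <- !(ep$edge | sp$edge)
    per_epoch <- vapply(epoch_idx, function(ii) {
      jj <- ii[keep[ii]]
      if (length(jj) == 0) return(NA_real_)
      Mod(mean(dphi[jj]))
    }, numeric(1))
    early <- per_epoch[half1]
    late <- per_epoch[setdiff(seq_len(ne), half1)]
    tt <- t.test(late, early)
    tibble(
      channel = eeg$channel_labels[ch],
      plv_early = mean(early, na.rm = TRUE), plv_late = mean(late, na.rm = TRUE),
      delta_plv = mean(late, na.rm = TRUE) - mean(early, na.rm = TRUE),
      t = unname(tt$statistic), p = tt$p.value
    )
  })
  res$p_adj <- p.adjust(res$p, method = "BH")
  res$significant <- res$p_adj < q
  class(res) <- c("plv_change", class(res))
  attr(res, "freq") <- freq
  res
}
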