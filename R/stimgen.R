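#' Metrical grid for a tempo
#'
#' At tempo `bpm`, quarter notes recur at `bpm / 60` Hz and 16th, 32nd and
#' 64th notes at 4, 8 and 16 times that rate. At 120 bpm these are 2, 8, 16
#' and 32 Hz, so the 8/16/32 Hz modulation-rate conditions correspond to
#' 16th-, 32nd- and 64th-note rates and are integer multiples of each other.
#'
#' @param bpm beats per minute (> 0).
#' @return A tibble with one row per subdivision: `subdivision`, `rate_hz`.
#' @export
#' @examples
#' metrical_grid(120)
metrical_grid <- function(bpm = 120) {
  stopifnot(is.numeric(bpm), bpm > 0)
  q <- bpm / 60
  out <- tibble(
    subdivision = c("quarter", "eighth", "sixteenth", "thirty_second", "sixty_fourth"),
    rate_hz = q * c(1, 2, 4, 8, 16)
  )
  attr(out, "bpm") <- bpm
  out
}

#' @rdname metrical_grid
#' @param grid a [metrical_grid()] tibble.
#' @param subdivision one of the grid's subdivision names.
#' @export
grid_rate <- function(grid, subdivision) {
  grid$rate_hz[match(subdivision, grid$subdivision)]
}

#' Modulation recipe for one stimulus condition
#'
#' @param rate modulator rate in Hz.
#' @param depth nominal modulation depth in \[0, 1\]; 1 drives the sound
#'   energy to zero at modulator troughs.
#' @param band two-element Hz vector: the audio band the modulation is
#'   applied to (default 200-1000 Hz).
#' @param phase_anchor offset in seconds of the beat grid; modulator peaks
#'   fall on `phase_anchor + k / rate`.
#' @param crossfade_s crossfade length used when assembling sessions.
#' @return list of class `modulation_params`.
#' @export
modulation_params <- function(rate, depth, band = c(200, 1000),
                              phase_anchor = 0, crossfade_s = 2) {
  if (depth < 0 || depth > 1) abort("`depth` must be in [0, 1]", class = "ammod_invalid_parameter")
  if (rate <= 0) abort("`rate` must be positive", class = "ammod_invalid_parameter")
  if (band[1] <= 0 || band[1] >= band[2]) {
    abort("invalid application band", class = "ammod_invalid_parameter")
  }
  structure(
    list(rate = rate, depth = depth, band = band,
         phase_anchor = phase_anchor, crossfade_s = crossfade_s),
    class = "modulation_params"
  )
}

#' Raised-cosine amplitude modulator aligned to the beat grid
#'
#' `m(t) = (1 - d/2) + (d/2) cos(2 pi r (t - anchor))`: unity at beat-grid
#' points (peak level is depth-invariant) and `1 - d` at troughs, so full
#' depth (`d = 1`) silences the troughs.
#'
#' @param params a [modulation_params()].
#' @param duration_s duration in seconds.
#' @param sample_rate sampling rate of the returned waveform in Hz.
#' @return numeric vector of length `round(duration_s * sample_rate)`.
#' @export
make_modulator <- function(params, duration_s, sample_rate) {
  stopifnot(inherits(params, "modulation_params"), duration_s > 0)
  if (params$rate >= sample_rate / 2) {
    abort("modulator rate at or above Nyquist", class = "ammod_invalid_parameter")
  }
  t <- seq(0, by = 1 / sample_rate, length.out = round(duration_s * sample_rate))
  d <- params$depth
  (1 - d / 2) + (d / 2) * cos(2 * pi * params$rate * (t - params$phase_anchor))
}

# zero-phase FFT-domain band split with raised-cosine transitions; the
# out-of-band component is formed by exact subtraction so in + out == x
band_split <- function(x, sample_rate, band, transition = 50) {
  n <- length(x)
  f <- (0:(n - 1)) * sample_rate / n
  f <- pmin(f, sample_rate - f) # symmetric (two-sided) frequency axis
  w <- rep(0, n)
  lo <- band[1]; hi <- band[2]
  w[f >= lo + transition / 2 & f <= hi - transition / 2] <- 1
  rise <- f > lo - transition / 2 & f < lo + transition / 2
  w[rise] <- 0.5 - 0.5 * cos(pi * (f[rise] - (lo - transition / 2)) / transition)
  fall <- f > hi - transition / 2 & f < hi + transition / 2
  w[fall] <- 0.5 + 0.5 * cos(pi * (f[fall] - (hi - transition / 2)) / transition)
  in_band <- Re(fft(fft(x) * w, inverse = TRUE) / n)
  list(in_band = in_band, out_band = x - in_band)
}

#' Apply band-limited amplitude modulation to a track
#'
#' The signal is split into in-band (`params$band`, default 200 Hz-1 kHz)
#' and out-of-band components with complementary zero-phase filters that sum
#' exactly to the input; the in-band component is multiplied by the
#' grid-aligned modulator and the components are re-summed. Content outside
#' the band is untouched, so processed tracks differ from their originals
#' only in the modulation domain.
#'
#' @param track an [audio_track()].
#' @param params a [modulation_params()].
#' @param preserve_band_rms compensate the modulated band back to its
#'   original rms (default TRUE). A modulator with mean below one removes
#'   energy, which would lower the long-term level of the application band
#'   by several dB at high depth; the compensation keeps the audio-frequency
#'   spectrum of the processed track matched to the original, and — because
#'   the modulation spectrum is DC-normalized — leaves the modulation-domain
#'   analysis untouched.
#' @return the modulated `audio_track` (bpm metadata preserved).
#' @export
apply_modulation <- function(track, params, preserve_band_rms = TRUE) {
  stopifnot(inherits(track, "audio_track"), inherits(params, "modulation_params"))
  if (params$band[2] >= track$sample_rate / 2) {
    abort("application band reaches Nyquist", class = "ammod_invalid_parameter")
  }
  m <- make_modulator(params, n_samples(track) / track$sample_rate, track$sample_rate)
  m <- m[seq_len(n_samples(track))]
  out <- track$samples
  for (ch in seq_len(ncol(out))) {
    sp <- band_split(out[, ch], track$sample_rate, params$band)
    modded <- sp$in_band * m
    if (preserve_band_rms) {
      r0 <- sqrt(mean(sp$in_band^2))
      r1 <- sqrt(mean(modded^2))
      if (r1 > 0) modded <- modded * (r0 / r1)
    }
    out[, ch] <- sp$out_band + modded
  }
  audio_track(out, track$sample_rate, bpm = track$bpm)
}

#' Calibrate nominal depths to evenly stepped applied-depth metrics
#'
#' Applied modulation depth is quantified after processing as the
#' modulation-spectrum difference metric ([modspec_difference()]), because
#' the modulator interacts with the music. This routine finds nominal depths
#' whose metrics form an arithmetic progression (low, medium, high step up
#' evenly), by monotone bisection on nominal depth.
#'
#' @param track an [audio_track()].
#' @param rate modulator rate in Hz.
#' @param n_levels number of depth levels (default 3). With `n_levels = 1` a
#'   single depth whose metric is half the full-depth metric is returned.
#' @param d_max nominal depth of the highest level (default 0.95).
#' @param tol relative tolerance on each target metric (default 0.01).
#' @param band,... application band and extra arguments passed to
#'   [cochlear_filterbank()] (e.g. `n_channels`, `f_range`) to control the
#'   analysis cost.
#' @return tibble with `level`, `nominal_depth`, `depth_metric`.
#' @export
calibrate_depths <- function(track, rate, n_levels = 3, d_max = 0.95,
                             tol = 0.01, band = c(200, 1000), ...) {
  stopifnot(inherits(track, "audio_track"))
  if (max(abs(track$samples)) == 0) {
    abort("cannot calibrate depths on silence", class = "ammod_calibration_failure")
  }
  ms_orig <- modulation_spectrum(cochlear_filterbank(track, ...))
  metric_of <- function(d) {
    p <- modulation_params(rate, d, band = band)
    ms_p <- modulation_spectrum(cochlear_filterbank(apply_modulation(track, p), ...))
    modspec_difference(ms_orig, ms_p, rate = rate)$depth_metric
  }
  m_probe <- vapply(c(d_max / 3, 2 * d_max / 3, d_max), metric_of, numeric(1))
  if (any(diff(m_probe) <= 0) || m_probe[1] <= 0) {
    abort("depth metric is not increasing in nominal depth (degenerate input?)",
          class = "ammod_calibration_failure")
  }
  m_max <- m_probe[3]
  solve_depth <- function(target) {
    lo <- 0; hi <- d_max
    m_lo <- 0; m_hi <- m_max
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      m_mid <- metric_of(mid)
      if (abs(m_mid - target) <= tol * target) return(list(d = mid, m = m_mid))
      if (m_mid < target) { lo <- mid } else { hi <- mid }
      if (hi - lo < 1e-4) return(list(d = mid, m = m_mid))
    }
    list(d = (lo + hi) / 2, m = metric_of((lo + hi) / 2))
  }
  if (n_levels == 1) {
    s <- solve_depth(m_max / 2)
    return(tibble(level = "single", nominal_depth = s$d, depth_metric = s$m))
  }
  targets <- seq_len(n_levels) * m_max / n_levels
  depths <- numeric(n_levels)
  metrics <- numeric(n_levels)
  for (i in seq_len(n_levels - 1)) {
    s <- solve_depth(targets[i])
    depths[i] <- s$d; metrics[i] <- s$m
  }
  depths[n_levels] <- d_max; metrics[n_levels] <- m_max
  lv <- if (n_levels == 3) c("low", "medium", "high") else paste0("level", seq_len(n_levels))
  tibble(level = lv, nominal_depth = depths, depth_metric = metrics)
}

#' Assemble a listening session from condition variants
#'
#' With `mode = "parallel"` (default) all tracks are equal-length,
#' time-aligned variants of the same underlying music; the session plays
#' consecutive blocks from consecutive entries of `order`, switching variant
#' at block boundaries with smooth raised-cosine crossfades, so the playback
#' position in the underlying music is continuous (no restart). Because
#' parallel variants are coherent (same underlying signal), the fade weights
#' are amplitude-complementary — identical variants pass through unchanged.
#' With `mode = "append"` tracks are separate (uncorrelated) blocks joined
#' by equal-power overlap-add; the total duration is the summed length
#' minus the overlapped fades.
#'
#' @param tracks named list of [audio_track()] variants (same length and
#'   sample rate for `"parallel"`).
#' @param order character vector of names into `tracks`, one per block.
#' @param crossfade_s crossfade duration in seconds.
#' @param mode `"parallel"` or `"append"`.
#' @return an `audio_track`.
#' @export
assemble_session <- function(tracks, order, crossfade_s = 2,
                             mode = c("parallel", "append")) {
  mode <- match.arg(mode)
  stopifnot(all(order %in% names(tracks)))
  srs <- vapply(tracks, function(t) t$sample_rate, numeric(1))
  if (length(unique(srs)) != 1) abort("sample rates differ", class = "ammod_invalid_input")
  sr <- srs[[1]]
  ncf <- round(crossfade_s * sr)
  theta <- seq(0, pi / 2, length.out = ncf)
  if (mode == "parallel") {
    # coherent material: amplitude-complementary raised-cosine weights
    w_out <- cos(theta)^2; w_in <- sin(theta)^2
  } else {
    # uncorrelated blocks: equal-power weights
    w_out <- cos(theta); w_in <- sin(theta)
  }

  if (mode == "parallel") {
    lens <- vapply(tracks, n_samples, numeric(1))
    if (length(unique(lens)) != 1) {
      abort("parallel variants must be time-aligned and equal length", class = "ammod_invalid_input")
    }
    n <- lens[[1]]
    nb <- length(order)
    block_len <- n %/% nb
    mono_all <- ncol(tracks[[order[1]]]$samples)
    out <- matrix(0, n, mono_all)
    for (b in seq_len(nb)) {
      i0 <- (b - 1) * block_len + 1
      i1 <- if (b == nb) n else b * block_len
      out[i0:i1, ] <- tracks[[order[b]]]$samples[i0:i1, , drop = FALSE]
    }
    # crossfade across each boundary: previous variant fades out, next in
    for (b in seq_len(nb - 1)) {
      if (order[b] == order[b + 1]) next
      ctr <- b * block_len
      idx <- (ctr - ncf %/% 2 + 1):(ctr - ncf %/% 2 + ncf)
      idx <- idx[idx >= 1 & idx <= n]
      k <- seq_along(idx)
      out[idx, ] <- tracks[[order[b]]]$samples[idx, , drop = FALSE] * w_out[k] +
        tracks[[order[b + 1]]]$samples[idx, , drop = FALSE] * w_in[k]
    }
    return(audio_track(out, sr, bpm = tracks[[order[1]]]$bpm))
  }

  # append mode: equal-power overlap-add
  segs <- lapply(order, function(nm) tracks[[nm]]$samples)
  nchan <- ncol(segs[[1]])
  total <- sum(vapply(segs, nrow, numeric(1))) - (length(segs) - 1) * ncf
  out <- matrix(0, total, nchan)
  pos <- 0
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    if (i > 1) s[seq_len(ncf), ] <- s[seq_len(ncf), , drop = FALSE] * w_in
    if (i < length(segs)) {
      tail_idx <- (nrow(s) - ncf + 1):nrow(s)
      s[tail_idx, ] <- s[tail_idx, , drop = FALSE] * w_out
    }
    out[pos + seq_len(nrow(s)), ] <- out[pos + seq_len(nrow(s)), , drop = FALSE] + s
    pos <- pos + nrow(s) - ncf
  }
  audio_track(out, sr, bpm = tracks[[order[1]]]$bpm)
}

#' Validate that a processed track differs only in the modulation domain
#'
#' Three checks mirror the stimulus-validation analysis used for
#' parametric-modulation stimuli: (a) the long-term third-octave spectrum of
#' the processed track deviates at most `spectrum_tol_db` (default 1 dB) per
#' band from the original over 100 Hz-8 kHz; (b) the modulation-spectrum
#' difference map has its broadband peak at the applied modulator rate; (c)
#' at most `oob_tol` (default 5%) of the absolute modulation-difference
#' energy lies in cochlear channels outside the application band.
#'
#' @param orig,proc [audio_track()]s of equal length and sample rate.
#' @param band application band in Hz used for check (c).
#' @param rate nominal modulator rate (Hz) for the difference metric; `NULL`
#'   uses the broadband-difference argmax.
#' @param spectrum_tol_db,oob_tol pass thresholds.
#' @param ... passed to [cochlear_filterbank()].
#' @return list of class `stimulus_validation`: `spectrum` (tibble of
#'   third-octave deviations), `max_spectrum_dev_db`, `difference`
#'   ([modspec_difference()]), `peak_rate`, `out_of_band_fraction` and
#'   logical `passed` fields.
#' @export
validate_stimulus <- function(orig, proc, band = c(200, 1000), rate = NULL,
                              spectrum_tol_db = 1, oob_tol = 0.05, ...) {
  if (n_samples(orig) != n_samples(proc) || orig$sample_rate != proc$sample_rate) {
    abort("tracks must have equal length and sample rate", class = "ammod_invalid_input")
  }
  spec_tab <- third_octave_deviation(orig, proc)
  max_dev <- max(abs(spec_tab$deviation_db), na.rm = TRUE)

  ms_o <- modulation_spectrum(cochlear_filterbank(orig, ...))
  ms_p <- modulation_spectrum(cochlear_filterbank(proc, ...))
  d <- modspec_difference(ms_o, ms_p, rate = rate)
  peak <- suppressWarnings(find_modulation_peak(d, c(2, min(50, max(d$mod_freqs)))))

  abs_d <- abs(d$difference)
  # a channel is out-of-band only if its cochlear passband (center +/- one
  # ERB) misses the application band entirely; a channel whose filter skirts
  # reach into the band legitimately responds to in-band modulation
  erb <- d$center_freqs / 9.26449 + 24.7
  out_band <- (d$center_freqs + erb) < band[1] | (d$center_freqs - erb) > band[2]
  tot <- sum(abs_d)
  oob <- if (tot > 0) sum(abs_d[out_band, , drop = FALSE]) / tot else 0

  structure(
    list(
      spectrum = spec_tab, max_spectrum_dev_db = max_dev,
      difference = d, peak_rate = peak, out_of_band_fraction = oob,
      spectrum_passed = max_dev <= spectrum_tol_db,
      band_passed = oob <= oob_tol,
      passed = max_dev <= spectrum_tol_db && oob <= oob_tol
    ),
    class = "stimulus_validation"
  )
}

third_octave_deviation <- function(orig, proc, f_lo = 100, f_hi = 8000) {
  x <- to_mono(orig)$samples[, 1]
  y <- to_mono(proc)$samples[, 1]
  sr <- orig$sample_rate
  n <- length(x)
  f <- (0:(n %/% 2)) * sr / n
  px <- Mod(fft(x)[1:(n %/% 2 + 1)])^2
  py <- Mod(fft(y)[1:(n %/% 2 + 1)])^2
  centers <- 1000 * 2^(seq(-10, 10) / 3)
  centers <- centers[centers >= f_lo & centers <= min(f_hi, sr / 2 / 2^(1 / 6))]
  dev <- vapply(centers, function(fc) {
    sel <- f >= fc / 2^(1 / 6) & f < fc * 2^(1 / 6)
    po <- sum(px[sel]); pp <- sum(py[sel])
    if (po <= 0 || pp <= 0) return(NA_real_)
    10 * log10(pp / po)
  }, numeric(1))
  tibble(center_hz = centers, deviation_db = dev)
}

#' @export
print.stimulus_validation <- function(x, ...) {
  cat(sprintf(
    "<stimulus_validation> %s\n  spectrum: max |dev| %.3f dB (%s)\n  modulation peak: %s Hz\n  out-of-band difference energy: %.2f%% (%s)\n",
    if (x$passed) "PASS" else "FAIL",
    x$max_spectrum_dev_db, if (x$spectrum_passed) "pass" else "fail",
    format(x$peak_rate), 100 * x$out_of_band_fraction,
    if (x$band_passed) "pass" else "fail"
  ))
  invisible(x)
}
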