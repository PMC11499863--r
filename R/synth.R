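#' Synthesize music-like audio on a metrical grid
#'
#' A deterministic (seeded) stand-in for focus music: decaying tone events
#' (pentatonic pitches, carriers mostly in the 200-1000 Hz application band)
#' placed on quarter/eighth/sixteenth subdivisions of a 120-bpm grid, a
#' percussive noise burst on each quarter note, and a low-level pink-noise
#' bed. Event trains at the 16th-note rate put modulation energy at 8 Hz
#' and its harmonics.
#'
#' @param duration_s duration in seconds (>= 10).
#' @param bpm tempo (default 120).
#' @param note_pattern subdivisions that carry tone events (subset of the
#'   [metrical_grid()] subdivisions).
#' @param sample_rate sampling rate in Hz (default 44100).
#' @param seed RNG seed; same seed gives bit-identical output.
#' @return an [audio_track()] with `bpm` metadata, peak-normalized to 0.5.
#' @export
synth_music <- function(duration_s = 30, bpm = 120,
                        note_pattern = c("quarter", "eighth", "sixteenth"),
                        sample_rate = 44100, seed = 1) {
  if (duration_s < 10) abort("`duration_s` must be >= 10 s", class = "ammod_invalid_parameter")
  grid <- metrical_grid(bpm)
  if (!all(note_pattern %in% grid$subdivision) || length(note_pattern) == 0) {
    abort("unknown or empty `note_pattern`", class = "ammod_invalid_parameter")
  }
  set.seed(seed)
  n <- round(duration_s * sample_rate)
  x <- numeric(n)
  # A-minor pentatonic across two octaves, mostly inside 200-1000 Hz
  pitches <- c(220, 261.63, 293.66, 329.63, 392, 440, 523.25, 587.33, 659.26, 784)
  amp <- c(quarter = 0.9, eighth = 0.55, sixteenth = 0.35,
           thirty_second = 0.25, sixty_fourth = 0.2)
  for (sub in note_pattern) {
    rate <- grid_rate(grid, sub)
    onsets <- seq(0, duration_s - 1 / rate, by = 1 / rate)
    f0 <- sample(pitches, length(onsets), replace = TRUE)
    dur <- min(0.9 / rate, 0.35)
    ne <- round(dur * sample_rate)
    tt <- seq(0, by = 1 / sample_rate, length.out = ne)
    env <- exp(-tt / (dur / 4)) * (1 - exp(-tt / 0.004))
    for (i in seq_along(onsets)) {
      i0 <- round(onsets[i] * sample_rate) + 1
      i1 <- min(i0 + ne - 1, n)
      seg <- seq_len(i1 - i0 + 1)
      tone <- sin(2 * pi * f0[i] * tt[seg]) + 0.4 * sin(2 * pi * 2 * f0[i] * tt[seg])
      x[i0:i1] <- x[i0:i1] + amp[[sub]] * env[seg] * tone
    }
  }
  # percussive burst on each quarter note
  q_rate <- grid_rate(grid, "quarter")
  nb <- round(0.03 * sample_rate)
  benv <- exp(-seq(0, by = 1 / sample_rate, length.out = nb) / 0.008)
  for (on in seq(0, duration_s - 0.05, by = 1 / q_rate)) {
    i0 <- round(on * sample_rate) + 1
    i1 <- min(i0 + nb - 1, n)
    x[i0:i1] <- x[i0:i1] + 0.5 * benv[seq_len(i1 - i0 + 1)] * rnorm(i1 - i0 + 1)
  }
  # low-level pink bed (~ -26 dB below the events)
  bed <- pink_noise_vector(n, alpha = 1)
  x <- x + 0.05 * bed / sd(bed)
  out <- audio_track(x, sample_rate, bpm = bpm)
  peak_normalize(out, 0.5)
}

# 1/f^alpha noise by spectral shaping of white gaussian noise
pink_noise_vector <- function(n, alpha = 1) {
  nf <- n %/% 2
  re <- rnorm(nf); im <- rnorm(nf)
  half <- (re + 1i * im) * (1:nf)^(-alpha / 2)
  if (n %% 2 == 0) {
    spec <- c(0, half[1:(nf - 1)], Re(half[nf]), Conj(rev(half[1:(nf - 1)])))
  } else {
    spec <- c(0, half, Conj(rev(half)))
  }
  Re(fft(spec, inverse = TRUE)) / n
}

#' Synthesize pink (1/f) noise
#'
#' Spectral-shaping generator: white Gaussian spectrum scaled by
#' `f^(-alpha/2)`. With `alpha = 1` the power spectral density falls at
#' -3 dB/octave (within +/- 0.5 dB over 100 Hz-4 kHz), the classic pink
#' spectrum that falls off with increasing frequency like many natural
#' auditory environments; `alpha = 0` gives white noise.
#'
#' @param duration_s duration in seconds (> 0).
#' @param sample_rate sampling rate in Hz.
#' @param seed RNG seed (bit-identical output per seed).
#' @param alpha spectral exponent in \[0, 2\].
#' @return an [audio_track()] peak-normalized to 0.5.
#' @export
synth_pink_noise <- function(duration_s, sample_rate = 44100, seed = 1, alpha = 1) {
  if (duration_s <= 0) abort("`duration_s` must be positive", class = "ammod_invalid_parameter")
  if (alpha < 0 || alpha > 2) abort("`alpha` must be in [0, 2]", class = "ammod_invalid_parameter")
  set.seed(seed)
  x <- pink_noise_vector(round(duration_s * sample_rate), alpha)
  peak_normalize(audio_track(x, sample_rate), 0.5)
}

#' Fit the PSD slope of a track in dB/octave
#'
#' Welch PSD on log2-frequency; least-squares slope over `f_range`.
#' Used to check pink-noise calibration (-3 dB/octave for 1/f power).
#'
#' @param track an [audio_track()].
#' @param f_range fit range in Hz (default 100-4000).
#' @return slope in dB per octave.
#' @export
psd_slope <- function(track, f_range = c(100, 4000)) {
  x <- to_mono(track)$samples[, 1]
  fs <- track$sample_rate
  nseg <- min(length(x), 2^14)
  starts <- seq(1, length(x) - nseg + 1, by = nseg %/% 2)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  acc <- numeric(nseg %/% 2 + 1)
  for (s in starts) {
    seg <- (x[s:(s + nseg - 1)] - mean(x[s:(s + nseg - 1)])) * win
    acc <- acc + Mod(fft(seg)[1:(nseg %/% 2 + 1)])^2
  }
  f <- (0:(nseg %/% 2)) * fs / nseg
  sel <- f >= f_range[1] & f <= f_range[2]
  fit <- lm(I(10 * log10(acc[sel])) ~ log2(f[sel]))
  unname(coef(fit)[2])
}

#' Coupling specification for synthetic EEG
#'
#' @param freqs target frequencies in Hz.
#' @param strengths per-frequency coupling strengths (>= 0, recycled).
#' @param drift linear fractional change of strength across the recording
#'   (e.g. 1 ramps from 0.5x to 1.5x the nominal strength; recycled).
#' @param channel_weights per-channel gain vector (default all 1).
#' @param snr_db signal-to-noise ratio per channel in dB.
#' @param alpha background-noise spectral exponent (1/f^alpha), in \[0, 2\].
#' @return list of class `coupling_spec`.
#' @export
coupling_spec <- function(freqs, strengths = 1, drift = 0, channel_weights = NULL,
                          snr_db = 0, alpha = 1) {
  if (any(strengths < 0)) abort("strengths must be >= 0", class = "ammod_invalid_parameter")
  if (alpha < 0 || alpha > 2) abort("alpha must be in [0, 2]", class = "ammod_invalid_parameter")
  structure(
    list(freqs = freqs, strengths = rep(strengths, length.out = length(freqs)),
         drift = rep(drift, length.out = length(freqs)),
         channel_weights = channel_weights, snr_db = snr_db, alpha = alpha),
    class = "coupling_spec"
  )
}

#' Synthesize EEG phase-locked to a stimulus envelope
#'
#' Each channel is a sum of cosine components riding the instantaneous
#' phase of the stimulus envelope narrowband-filtered at each coupling
#' frequency (so phase-locking targets hold by construction), plus 1/f^alpha
#' background noise scaled to `snr_db`. A per-frequency linear drift scales
#' coupling strength across the recording, emulating entrainment that
#' builds up or washes out over a session.
#'
#' @param stim an [audio_track()] (or a numeric envelope already at
#'   `sample_rate`).
#' @param spec a [coupling_spec()].
#' @param n_channels number of channels (default 8; labels from a 10-20
#'   montage).
#' @param sample_rate EEG rate in Hz (default 250).
#' @param duration_s recording length; at most the stimulus duration.
#' @param seed RNG seed.
#' @return an [eeg_recording()].
#' @export
synth_eeg <- function(stim, spec, n_channels = 8, sample_rate = 250,
                      duration_s = NULL, seed = 1) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (any(spec$freqs >= sample_rate / 2)) {
    abort("coupling frequency at or above Nyquist", class = "ammod_invalid_parameter")
  }
  env <- if (inherits(stim, "audio_track")) {
    stimulus_envelope_for_plv(stim, sample_rate)
  } else as.numeric(stim)
  duration_s <- duration_s %||% (length(env) / sample_rate)
  n <- round(duration_s * sample_rate)
  if (n > length(env)) {
    abort("requested duration exceeds the stimulus", class = "ammod_invalid_parameter")
  }
  env <- env[seq_len(n)]
  labels <- c("Fz", "F3", "F4", "Cz", "C3", "C4", "Pz", "Oz",
              "Fp1", "Fp2", "F7", "F8", "C1", "C2", "P3", "P4",
              "P7", "P8", "O1", "O2", "T7", "T8", "F1", "F2")
  if (n_channels > length(labels)) labels <- c(labels, paste0("Ch", seq_len(n_channels)))
  labels <- labels[seq_len(n_channels)]
  w <- spec$channel_weights %||% rep(1, n_channels)

  set.seed(seed)
  ramp01 <- (seq_len(n) - 1) / max(n - 1, 1) - 0.5
  sig <- matrix(0, n_channels, n)
  offsets <- runif(n_channels, -pi, pi)
  for (j in seq_along(spec$freqs)) {
    if (spec$strengths[j] == 0) next
    ph <- narrowband_phase(env, spec$freqs[j], sample_rate)$phase
    gain <- spec$strengths[j] * (1 + spec$drift[j] * ramp01)
    for (ch in seq_len(n_channels)) {
      sig[ch, ] <- sig[ch, ] + w[ch] * gain * cos(ph + offsets[ch])
    }
  }
  data <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels)) {
    noise <- pink_noise_vector(n, spec$alpha)
    noise <- noise / sd(noise)
    p_sig <- mean(sig[ch, ]^2)
    scale <- if (p_sig > 0) sqrt(p_sig / 10^(spec$snr_db / 10)) else 1
    data[ch, ] <- sig[ch, ] + scale * noise
  }
  eeg_recording(data, sample_rate, labels)
}

#' Effect structure for a simulated SART cohort
#'
#' @param baseline_dprime sensitivity in the baseline condition.
#' @param condition_offsets named numeric: additive d' offset per condition.
#' @param block_slope linear d' change over blocks (per unit of the
#'   block covariate, which runs -1 to +1 from first to last block).
#' @param asrs_interaction coefficient of `z(ASRS) x target-condition x
#'   block` on d' (positive = the target condition's benefit grows over
#'   blocks for high-ASRS subjects).
#' @param interaction_condition condition the interaction applies to.
#' @param criterion SDT response criterion (0 = unbiased).
#' @param rt_meanlog,rt_sdlog lognormal reaction-time parameters.
#' @return list of class `effect_map`.
#' @export
effect_map <- function(baseline_dprime = 2, condition_offsets = c(none = 0),
                       block_slope = 0, asrs_interaction = 0,
                       interaction_condition = "16", criterion = 0,
                       rt_meanlog = log(0.35), rt_sdlog = 0.25) {
  if (rt_sdlog <= 0) abort("rt_sdlog must be > 0", class = "ammod_invalid_parameter")
  structure(
    list(baseline_dprime = baseline_dprime, condition_offsets = condition_offsets,
         block_slope = block_slope, asrs_interaction = asrs_interaction,
         interaction_condition = interaction_condition, criterion = criterion,
         rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog),
    class = "effect_map"
  )
}

#' Simulate a SART cohort with a signal-detection agent
#'
#' Per subject, an ASRS score is drawn from a discretized truncated normal;
#' per trial, an agent with cell sensitivity
#' `d' = baseline + offset(condition) + block_slope * l(block) +
#' asrs_interaction * z(ASRS) * I(condition == target) * l(block)`
#' and fixed criterion presses with probability `Phi(d'/2 - c)` on go trials
#' and `Phi(-d'/2 - c)` on no-go trials (so the recovered d' equals the cell
#' d' in expectation), emitting lognormal reaction times for presses.
#'
#' @param n_subjects cohort size (>= 2).
#' @param schedule a [generate_schedule()] tibble with condition labels.
#' @param effects an [effect_map()].
#' @param asrs_dist list with `mean`, `sd`, `min`, `max` of the discretized
#'   truncated-normal ASRS distribution (defaults 30, 12, 0, 72).
#' @param seed RNG seed.
#' @return list with `logs` (tibble: `subject`, `trial`, `pressed`, `rt_s`)
#'   and `profiles` (tibble: `subject`, `asrs_score`, `asrs_group` by median
#'   split).
#' @export
synth_cohort <- function(n_subjects, schedule, effects,
                         asrs_dist = list(mean = 30, sd = 12, min = 0, max = 72),
                         seed = 1) {
  stopifnot(inherits(effects, "effect_map"))
  if (n_subjects < 2) abort("need >= 2 subjects", class = "ammod_invalid_parameter")
  set.seed(seed)
  asrs <- round(pmin(pmax(rnorm(n_subjects, asrs_dist$mean, asrs_dist$sd),
                          asrs_dist$min), asrs_dist$max))
  z_asrs <- (asrs - asrs_dist$mean) / asrs_dist$sd
  # block covariate: presentation position within each condition (a
  # condition's earlier blocks get -1, later +1), matching how d' change
  # over time is scored relative to the baseline condition
  cond_block <- dplyr::distinct(schedule, .data$condition, .data$block) |>
    dplyr::group_by(.data$condition) |>
    dplyr::arrange(.data$block, .by_group = TRUE) |>
    dplyr::mutate(
      .l = if (dplyr::n() > 1) 2 * (dplyr::row_number() - 1) / (dplyr::n() - 1) - 1 else 0
    ) |>
    dplyr::ungroup()
  offs <- effects$condition_offsets
  cond <- as.character(schedule$condition)
  off_trial <- ifelse(cond %in% names(offs), offs[cond], 0)
  lb_trial <- cond_block$.l[match(paste(schedule$condition, schedule$block),
                                  paste(cond_block$condition, cond_block$block))]
  is_tgt_cond <- as.numeric(cond == effects$interaction_condition)

  logs <- purrr::map_dfr(seq_len(n_subjects), function(s) {
    dp <- effects$baseline_dprime + off_trial +
      effects$block_slope * lb_trial +
      effects$asrs_interaction * z_asrs[s] * is_tgt_cond * lb_trial
    p_press <- ifelse(schedule$is_target,
                      pnorm(-dp / 2 - effects$criterion),
                      pnorm(dp / 2 - effects$criterion))
    pressed <- runif(nrow(schedule)) < p_press
    rt <- ifelse(pressed,
                 pmin(rlnorm(nrow(schedule), effects$rt_meanlog, effects$rt_sdlog),
                      schedule$digit_dur_s + schedule$mask_dur_s - 1e-3),
                 NA_real_)
    tibble(subject = sprintf("s%03d", s), trial = schedule$trial,
           pressed = pressed, rt_s = rt)
  })
  profiles <- tibble(
    subject = sprintf("s%03d", seq_len(n_subjects)),
    asrs_score = asrs,
    asrs_group = ifelse(asrs > median(asrs), "high", "low")
  )
  list(logs = logs, profiles = profiles)
}
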