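# shared small fixtures; built once per test run, all seeded

fix_sr <- 16000
fix_fb <- function(tr, n_channels = 16) {
  cochlear_filterbank(tr, n_channels = n_channels, f_range = c(50, 7000))
}

# 12-s music-like track at 16 kHz (cheap enough for repeated analysis)
fix_music <- synth_music(12, bpm = 120, sample_rate = fix_sr, seed = 101)

# a hand-built cochleagram with known envelopes (for estimator oracles)
make_cochleagram <- function(envelopes, center_freqs, frame_rate) {
  structure(
    list(envelopes = envelopes, center_freqs = center_freqs, frame_rate = frame_rate),
    class = "cochleagram"
  )
}

tone_track <- function(freq, duration_s, sr = fix_sr, amp = 0.5, am_rate = NULL,
                       am_depth = 1) {
  t <- seq(0, by = 1 / sr, length.out = round(duration_s * sr))
  env <- if (is.null(am_rate)) 1 else (1 - am_depth / 2) + (am_depth / 2) * cos(2 * pi * am_rate * t)
  audio_track(amp * env * sin(2 * pi * freq * t), sr)
}

trimmed_cv <- function(e, trim = 0.1) {
  n <- length(e)
  e <- e[round(n * trim):round(n * (1 - trim))]
  sd(e) / mean(e)
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  cumsum(c(p[1], dp))
}

# direct FFT dominant frequency of a vector (independent oracle)
fft_peak <- function(x, fs, f_min = 1) {
  n <- length(x)
  p <- Mod(fft(x - mean(x))[1:(n %/% 2 + 1)])^2
  f <- (0:(n %/% 2)) * fs / n
  sel <- f >= f_min
  f[sel][which.max(p[sel])]
}
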