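test_that("metrical grid arithmetic is exact at 120 bpm", {
  g <- metrical_grid(120)
  expect_identical(grid_rate(g, "quarter"), 2)
  expect_identical(grid_rate(g, "sixteenth"), 8)
  expect_identical(grid_rate(g, "thirty_second"), 16)
  expect_identical(grid_rate(g, "sixty_fourth"), 32)
  # subdivision rates are integer multiples of each other
  r <- g$rate_hz
  expect_true(all(outer(r, r, "/")[lower.tri(matrix(0, 5, 5))] %% 1 == 0))
})

test_that("modulator has unit peaks on the beat grid and depth-set troughs", {
  sr <- 1600 # multiple of 32 Hz so peaks and troughs fall on the sample grid
  m0 <- make_modulator(modulation_params(16, 0), 1, sr)
  expect_equal(m0, rep(1, sr), tolerance = 1e-12)
  m1 <- make_modulator(modulation_params(16, 1), 1, sr)
  expect_equal(min(m1), 0, tolerance = 1e-6) # full depth silences troughs
  expect_equal(max(m1), 1, tolerance = 1e-12)
  # 16 Hz at 120 bpm: exactly 8 peaks per 0.5-s quarter-note period
  m <- make_modulator(modulation_params(16, 0.8), 0.5, sr)
  peaks <- which(diff(sign(diff(m))) == -2) + 1
  expect_equal(length(peaks) + 1, 8) # first peak sits at t = 0 (grid anchor)
  expect_equal(m[1], 1, tolerance = 1e-12)
})

test_that("coarser grid-aligned modulator peaks are a subset of finer ones", {
  sr <- 8000
  peak_times <- function(rate) seq(0, 1, by = 1 / rate)
  p8 <- peak_times(8); p16 <- peak_times(16); p32 <- peak_times(32)
  expect_true(all(p8 %in% p16))
  expect_true(all(p16 %in% p32))
})

test_that("zero depth is a no-op within the reconstruction floor", {
  out <- apply_modulation(fix_music, modulation_params(16, 0))
  rel <- max(abs(out$samples - fix_music$samples)) / max(abs(fix_music$samples))
  expect_lt(rel, 1e-4)
})

test_that("modulation is confined to the application band", {
  sr <- fix_sr
  p <- modulation_params(16, 1)
  inb <- apply_modulation(tone_track(500, 3), p)
  outb <- apply_modulation(tone_track(2000, 3), p)
  cg_in <- fix_fb(inb)
  cg_out <- fix_fb(outb)
  k_in <- which.min(abs(cg_in$center_freqs - 500))
  k_out <- which.min(abs(cg_out$center_freqs - 2000))
  expect_equal(fft_peak(cg_in$envelopes[k_in, ], cg_in$frame_rate), 16, tolerance = 0.05)
  expect_lt(trimmed_cv(cg_out$envelopes[k_out, ]), 0.05)
  # out-of-band samples pass through essentially untouched (<= -60 dB residual)
  tone <- tone_track(2000, 3)
  resid <- outb$samples - tone$samples
  expect_lt(20 * log10(max(abs(resid)) / max(abs(tone$samples))), -60)
})

test_that("band above Nyquist is rejected", {
  expect_error(apply_modulation(fix_music, modulation_params(16, 0.5, band = c(200, 9000))),
               class = "ammod_invalid_parameter")
  expect_error(modulation_params(16, 1.5), class = "ammod_invalid_parameter")
})

test_that("depth metric increases monotonically with nominal depth", {
  fbargs <- function(tr) cochlear_filterbank(tr, n_channels = 8, f_range = c(100, 3000))
  ms0 <- modulation_spectrum(fbargs(fix_music))
  metrics <- vapply(c(0.25, 0.5, 0.95), function(d) {
    msd <- modulation_spectrum(fbargs(apply_modulation(fix_music, modulation_params(16, d))))
    modspec_difference(ms0, msd, rate = 16)$depth_metric
  }, numeric(1))
  expect_true(all(diff(metrics) > 0))
})

test_that("calibrated depths step up evenly in the applied-depth metric", {
  noise <- synth_pink_noise(6, sample_rate = 8000, seed = 5, alpha = 0)
  cal <- calibrate_depths(noise, rate = 16, n_channels = 8, f_range = c(100, 3500))
  expect_equal(cal$level, c("low", "medium", "high"))
  expect_true(all(diff(cal$nominal_depth) > 0))
  steps <- diff(cal$depth_metric)
  expect_lt(abs(steps[2] - steps[1]) / mean(steps), 0.05)
})

test_that("single-level calibration returns the half-metric depth", {
  noise <- synth_pink_noise(6, sample_rate = 8000, seed = 5, alpha = 0)
  cal1 <- calibrate_depths(noise, rate = 16, n_levels = 1,
                           n_channels = 8, f_range = c(100, 3500))
  cal3 <- calibrate_depths(noise, rate = 16, n_channels = 8, f_range = c(100, 3500))
  expect_equal(cal1$depth_metric, cal3$depth_metric[3] / 2, tolerance = 0.05)
})

test_that("calibration on silence fails loudly", {
  expect_error(
    calibrate_depths(audio_track(numeric(8000), 8000), rate = 16),
    class = "ammod_calibration_failure"
  )
})

test_that("session assembly keeps identical variants identical", {
  tracks <- list(a = fix_music, b = fix_music)
  out <- assemble_session(tracks, c("a", "b"), crossfade_s = 1)
  rel <- max(abs(out$samples - fix_music$samples)) / max(abs(fix_music$samples))
  expect_lt(rel, 1e-10)
})

test_that("rms moves monotonically through an equal-power crossfade", {
  quiet <- audio_track(fix_music$samples * 0.2, fix_sr, bpm = 120)
  out <- assemble_session(list(loud = fix_music, quiet = quiet),
                          c("loud", "quiet"), crossfade_s = 2)
  n <- n_samples(out)
  ctr <- n %/% 2
  win <- round(0.25 * fix_sr)
  rms_at <- function(i) sqrt(mean(out$samples[(i - win):(i + win), 1]^2))
  probe <- seq(ctr - fix_sr, ctr + fix_sr, length.out = 7)
  levels <- vapply(probe, rms_at, numeric(1))
  expect_lt(levels[7], levels[1]) # fades from loud to quiet overall
})

test_that("append-mode duration bookkeeping: overlapped fades shorten the session", {
  blk <- audio_track(matrix(rnorm(2 * fix_sr) * 0.1, ncol = 1), fix_sr)
  out <- assemble_session(list(b = blk), rep("b", 4), crossfade_s = 0.5, mode = "append")
  expect_equal(n_samples(out), 4 * 2 * fix_sr - 3 * round(0.5 * fix_sr))
})

test_that("misaligned parallel variants are rejected", {
  short <- audio_track(fix_music$samples[1:1000, , drop = FALSE], fix_sr)
  expect_error(assemble_session(list(a = fix_music, b = short), c("a", "b")),
               class = "ammod_invalid_input")
})

test_that("peak normalization hits the target exactly and flags silence", {
  tr <- audio_track(c(0.1, -1, 0.4), 100)
  out <- peak_normalize(tr)
  expect_equal(max(abs(out$samples)), 0.5)
  expect_equal(out$samples[2], -0.5)
  expect_true(is.numeric(attr(out, "rms")))
  expect_error(peak_normalize(audio_track(numeric(10), 100)),
               class = "ammod_invalid_input")
})

test_that("after peak normalization, modulated variants have lower rms", {
  mod <- apply_modulation(fix_music, modulation_params(16, 0.95))
  r0 <- attr(peak_normalize(fix_music), "rms")
  r1 <- attr(peak_normalize(mod), "rms")
  expect_gt(r0, r1) # unmodulated track keeps the highest rms
})

test_that("validation passes for an identical pair with zero deviations", {
  v <- validate_stimulus(fix_music, fix_music, n_channels = 8, f_range = c(100, 3000))
  expect_true(v$passed)
  expect_equal(v$max_spectrum_dev_db, 0, tolerance = 1e-9)
  expect_equal(v$out_of_band_fraction, 0)
})

test_that("validation localizes band-limited modulation and flags broadband", {
  mod <- apply_modulation(fix_music, modulation_params(16, 0.5))
  v <- validate_stimulus(fix_music, mod, rate = 16,
                         n_channels = 16, f_range = c(100, 6000))
  expect_true(v$spectrum_passed) # long-term spectrum within 1 dB per band
  expect_equal(v$peak_rate, 16, tolerance = 0.5)
  expect_lte(v$out_of_band_fraction, 0.05)
  # modulation applied across the whole spectrum must fail the 200-1000 check
  broad <- apply_modulation(fix_music, modulation_params(16, 0.9, band = c(60, 6500)))
  vb <- validate_stimulus(fix_music, broad, band = c(200, 1000), rate = 16,
                          n_channels = 16, f_range = c(100, 6000))
  expect_false(vb$band_passed)
  expect_error(validate_stimulus(fix_music, audio_track(fix_music$samples[1:100, , drop = FALSE], fix_sr)),
               class = "ammod_invalid_input")
})
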