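---
title: "Modulation-domain analysis of music, neural entrainment and sustained attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modulation-domain analysis of music, neural entrainment and sustained attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ammod)
```

## Scope and model

Background music used as a focus aid often carries deliberate amplitude
modulation (AM) at rates far above what ordinary musical note values
produce. This package implements the computational chain needed to study
that phenomenon quantitatively: modulation-domain characterization of
audio, controlled insertion of AM into music, stimulus–brain phase-locking
analysis of EEG, and signal-detection scoring of a sustained-attention
task, together with seeded generators that emulate each kind of input.

The guiding assumptions are:

* The perceptually relevant description of "how a sound fluctuates" is the
  **modulation spectrum**: envelope-fluctuation power per cochlear channel
  as a function of modulation frequency, with the **broadband** profile
  being its channel sum.
* Acoustic AM at rate *r* entrains neural activity at *r*, measurable as
  stimulus–brain **phase-locking (PLV)** between narrowband-filtered EEG
  and the narrowband-filtered stimulus envelope.
* Effects of AM on sustained attention appear as d′ changes relative to
  unmodulated music, varying with modulation rate, time on task, and the
  listener's attentional difficulty (ASRS score).

## The acoustic front end

**Filterbank.** 32 gammatone channels (Slaney's all-pole IIR
approximation), ERB-spaced between 50 Hz and 8 kHz. The channel count is a
resolution/speed compromise; none of the downstream quantities is
sensitive to it once channels are dense enough that the 200 Hz–1 kHz
application band spans several channels (tests run with 8–24 channels).
Stereo audio is averaged to mono before analysis, the same convention used
when quoting rms levels of two-channel stimuli.

**Envelopes.** Per channel, the magnitude of the FFT-based analytic
signal, lowpassed at 150 Hz (4th-order Butterworth, zero phase) and
decimated to ≥ 400 Hz frames — enough margin to represent 0–100 Hz
modulations. Negative values after filtering are clipped at zero.

**Modulation estimator.** Welch-averaged periodograms of the demeaned
envelopes: Hann windows of 8 s (0.125 Hz resolution on a 30-s excerpt),
50% overlap. Per-channel power is divided by the squared mean envelope
(DC power), recorded in `normalization_tag`; this makes the spectrum
invariant to waveform scaling (tested to 1e-6 relative tolerance) so depth
comparisons are level-independent. Power is reported on a linear scale;
the depth metric below is defined on that scale.

**Depth metric.** The practical quantity "how much modulation did the
processing actually add" is operationalized as the channel-summed
difference between processed and original modulation spectra, integrated
over a ±1 Hz window centered on the modulator rate. It is zero for
identical inputs, strictly increasing in nominal depth, and invariant to
overall level.

## Inserting modulation

The modulator is a raised sinusoid,
`m(t) = (1 − d/2) + (d/2)·cos(2π·r·(t − anchor))`,
with unity peaks on the metrical grid so that peak level is
depth-invariant and a musical event amplified by a modulator peak at 8 Hz
is also amplified at 16 and 32 Hz (the rates are integer multiples and
grid-aligned at 120 bpm: 16th/32nd/64th-note rates). Full depth (d = 1)
silences the troughs. The shape was an open choice; a smooth sinusoid
minimizes spectral splatter.

The signal is split at 200 Hz and 1 kHz by complementary zero-phase
FFT-domain filters with 50-Hz raised-cosine transitions. The out-of-band
part is reconstructed by exact subtraction, so the split sums to the input
bit-exactly and zero depth is a strict no-op. Only the in-band part is
multiplied by `m(t)`.

**Band rms compensation.** Because `m(t)` has mean below one, plain
multiplication removes energy — about 4 dB from the band at near-full
depth — which would visibly change the long-term spectrum and defeat the
goal of stimuli that differ *only* in the modulation domain. The
modulated band is therefore rescaled to its original rms (a single
constant gain per channel of audio). The DC-normalized modulation
spectrum is invariant to that constant, so the depth metric and the
difference map are unaffected; only the spectral-balance validation
benefits. This is on by default and can be disabled.

**Depth calibration.** Nominal depth is not linear in applied depth (the
modulator interacts with the music's own envelope), so the three
experimental levels are calibrated: the high level is a fixed nominal
depth (0.95 by default), and lower levels are found by monotone bisection
so the applied-depth metrics form an arithmetic progression (tested to 5%
relative tolerance). With one requested level the convention is the depth
whose metric is half the full-depth metric.

**Validation.** `validate_stimulus()` checks that (a) every third-octave
band between 100 Hz and 8 kHz moved less than 1 dB, (b) the
modulation-difference map peaks at the applied rate, and (c) at most 5% of
the absolute modulation-difference energy lies in out-of-band cochlear
channels. A channel counts as out-of-band only if its passband (center ±
one ERB) misses the application band entirely: a channel centered at
166 Hz has a 43-Hz ERB and genuinely responds to 200-Hz-band modulation
through its skirts, and counting that response as leakage would make the
criterion unmeetable by construction rather than by design.

**Sessions.** Condition variants of the same underlying track are joined
with raised-cosine crossfades (2 s by default) on a shared timeline, so
the playback position never restarts. Because such variants are coherent,
the fade weights are amplitude-complementary (cos²/sin², summing to one):
equal-power weights would boost correlated material by up to 3 dB
mid-fade. A separate append mode joins unrelated blocks with equal-power
overlap-add, where total duration is the summed length minus overlapped
fades.

## Stimulus–brain coupling

**Stimulus signal.** EEG and audio live at very different rates, and
filtering raw audio at 1–50 Hz would capture near-DC pressure rather than
perceptual modulation. The stimulus signal for coupling analysis is the
broadband cochlear envelope, anti-alias lowpassed and resampled to the EEG
rate.

**Phase.** Complex Morlet filtering (7 cycles by default, configurable)
at each frequency of interest, applied identically to EEG and stimulus;
the phase is the argument of the filtered signal. Samples within three
cycles of either edge are flagged and excluded from all PLV estimates.

**PLV.** `|mean(exp(i·Δφ))|`, normalized by the sample count so the value
lies in [0, 1] — 1 for perfect locking (constant offsets included), with
a Rayleigh-distributed null around `sqrt(π/4)/sqrt(n)` for independent
phases. A widely used unnormalized variant (a plain sum over samples) is
unbounded; this package always divides by n and states so here
prominently because axis-reading and thresholding depend on it.

An important practical limit, verified numerically in the tests: at low
frequencies the Morlet bandwidth leaves few effective samples, so the PLV
null is large (≈ 0.2 at 1 Hz for 60 s of data). Null-level bounds like
"noise PLV < 0.1" are meaningful only above roughly 15 Hz at that
duration; interpret low-frequency PLV against a matched null, not an
absolute threshold. Closely spaced coupling peaks (e.g. 12/14/16 Hz) need
narrower filters than the 7-cycle default to resolve; `n_cycles` is a
parameter everywhere.

**Spectra, binned effects, change over time.** `plv_spectrum()` evaluates
1–50 Hz in 1-Hz bins per channel. `binned_effect_size()` averages PLV
over a montage group (10-20 label prefixes: frontal, central, parietal,
frontocentral, all), samples bin centers (multiples of the bin width) and
computes Cohen's d paired across bins; when coupling concentrates at
multiples of 4 Hz, the 4-Hz binning yields a much larger d than 1-Hz
binning — the qualitative signature of note-rate-locked entrainment. The
paired-across-bins reading of d is an interpretation (the sampling unit is
ambiguous in common usage); it is recorded here as such. Early-vs-late
change splits the recording into contiguous 10-s epochs, computes PLV per
epoch, and runs per-channel Welch t-tests (late vs early) with
Benjamini–Hochberg FDR at q = 0.05 across channels.

## Behavior

Schedules place exactly `round(n × 0.10)` no-go targets (digit 0) with no
two targets adjacent (standard practice; configurable off), non-target
digits uniform on 1–9, and a 1.15-s onset asynchrony (250 ms digit +
900 ms mask). Two presets cover the common layouts (1200 trials / 6
blocks; 1080 trials / 4 blocks).

d′ uses the log-linear correction (0.5 added to each count, 1 to each
total) so blocks with perfect rates stay finite; the correction is tagged
in the output. Note the correction is only symmetric for equal go/no-go
counts: an all-press responder on a 180/20 block scores
`qnorm(361/362) − qnorm(41/42) ≈ 0.79`, not 0.

Δd′ tables compare each condition against the no-modulation baseline by
presentation position within condition (a condition's first block against
the baseline's first block, and so on), because each block carries exactly
one condition. Group summaries report within-subject SEM: subject-mean
centering plus the Morey inflation `sqrt(m/(m−1))` over the m cells.

The rate × block × attentional-difficulty analysis is deliberately
re-operationalized from a repeated-measures mixed-effects ANOVA (whose
exact error strata are rarely recoverable from a text description) to an
equivalent-purpose per-subject contrast: quadratic weights (−1, +2, −1)
over 8/16/32 Hz — peaking at the medium rate — times linear weights
(−1, +1) over early/late, summed against each subject's Δd′ cells; the
statistic is the slope of that contrast on centered ASRS, with a
seeded permutation test on ASRS labels. The method string travels with
every result object.

## Synthetic data: what it does and does not emulate

All generators are pure functions of their configuration plus a seed.

* `synth_music()` places decaying tone events (pentatonic pitches, mostly
  inside 200 Hz–1 kHz) on quarter/eighth/sixteenth subdivisions of a
  120-bpm grid with a percussive quarter-note pulse and a low pink-noise
  bed, then peak-normalizes to 0.5. It reproduces the *metrical envelope
  structure* of focus music (event trains at 8 Hz and harmonics) but not
  melody, voice-leading or production features.
* `synth_pink_noise()` shapes white Gaussian spectra by `f^(−α/2)`;
  α = 1 gives the −3 dB/octave pink slope (fit-checked over
  100 Hz–4 kHz), α = 0 white noise.
* `synth_eeg()` builds each channel as cosines riding the stimulus
  envelope's narrowband phase at the coupling frequencies — so PLV targets
  hold by construction — plus 1/f^α noise at a set SNR, with optional
  linear strength drift across the recording (entrainment building up or
  washing out). It is not a forward head model: no volume conduction, no
  artifacts, no topography beyond per-channel weights.
* `synth_cohort()` draws ASRS scores from a discretized truncated normal
  (mean 30, sd 12 over 0–72) and simulates each trial with an SDT agent:
  press probability `Φ(d′/2 − c)` on go and `Φ(−d′/2 − c)` on no-go
  trials, so recovered d′ equals the designed cell d′ in expectation;
  reaction times are lognormal. Cell d′ composes a baseline, per-condition
  offsets, a linear block term and an ASRS × target-condition × block
  interaction.

Passing tests on these generators show that the *analysis chain is
correct and well calibrated* (parameter recovery, null calibration,
power at designed effects); they do not show that real music, real EEG or
real participants behave like the generators.

## Numerical choices and problem sizes

Default tolerances and sizes were chosen once, as analysis decisions:
0.125-Hz modulation resolution (8-s Welch windows); 400-Hz envelope
frames; 50-Hz band-split transitions; bisection to 1% of the target
metric in depth calibration; 10-s EEG epochs; permutation p-values with
199–1999 resamples depending on context. The test suite exercises the
pipeline at reduced sizes (12–30-s audio at 8–16 kHz, 8–24 cochlear
channels, 60–120-s EEG at 125–250 Hz, cohorts of 2–100 subjects,
2000 summary-level null datasets for type-I calibration), sizes at which
every recovery and calibration property stated above is met; the
demonstration pipeline `run_demo()` uses 60-s audio, 8-channel EEG and a
24-subject cohort.

Degenerate inputs are first-class: silence is rejected where an envelope
or calibration is required, all-go schedules are flagged as yielding no
d′, windows with fewer than two RTs give missing values rather than
errors, zero-variance effect-size denominators return a signed infinity
with a diagnostic, and peak search below a power floor returns `NA` with
a warning rather than inventing a peak.

## Known limitations

* The gammatone/ERB front end is a linear cochlear approximation; no
  compression, adaptation or efferent effects.
* The depth metric integrates a fixed ±1 Hz window; very low modulator
  rates (< 2 Hz) are not separable from DC on short excerpts.
* PLV at low frequencies needs long recordings (see above); the 1-Hz bins
  below ~5 Hz on 60-s data are dominated by the Rayleigh floor.
* The permutation contrast replaces, and does not numerically reproduce,
  a mixed-effects ANOVA F statistic; only sign/structure conclusions
  transfer.
* EEG preprocessing (referencing, artifact handling, channel
  interpolation) is assumed done upstream.
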