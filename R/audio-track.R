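#' Audio track container
#'
#' A lightweight container for sampled audio: a numeric matrix of samples
#' (rows = frames, columns = channels, values nominally in \[-1, 1\]), a
#' sampling rate in Hz, and optional beats-per-minute metadata used by the
#' metrical-grid machinery.
#'
#' @param samples numeric vector (mono) or matrix (frames x channels).
#' @param sample_rate sampling rate in Hz (> 0).
#' @param bpm optional tempo metadata in beats per minute.
#'
#' @return An object of class `audio_track`.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1 / 8000)
#' audio_track(sin(2 * pi * 440 * t), 8000)
audio_track <- function(samples, sample_rate, bpm = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    abort("`samples` must be a numeric vector or matrix.", class = "ammod_invalid_input")
  }
  if (nrow(samples) == 0) abort("empty audio", class = "ammod_invalid_input")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    abort("`sample_rate` must be a positive scalar.", class = "ammod_invalid_parameter")
  }
  if (!ncol(samples) %in% c(1L, 2L)) {
    abort("audio must be mono or stereo", class = "ammod_invalid_input")
  }
  structure(
    list(samples = samples, sample_rate = sample_rate, bpm = bpm),
    class = "audio_track"
  )
}

#' @export
print.audio_track <- function(x, ...) {
  cat(sprintf(
    "<audio_track> %d ch, %.3f s @ %g Hz%s\n",
    ncol(x$samples), nrow(x$samples) / x$sample_rate, x$sample_rate,
    if (!is.null(x$bpm)) sprintf(", %g bpm", x$bpm) else ""
  ))
  invisible(x)
}

#' Number of samples and duration helpers
#' @param track an [audio_track()].
#' @return `n_samples()`: integer count; `duration()`: seconds.
#' @export
n_samples <- function(track) nrow(track$samples)

#' @rdname n_samples
#' @export
track_duration <- function(track) nrow(track$samples) / track$sample_rate

#' Reduce a track to mono
#'
#' Stereo tracks are reduced by averaging the left and right channels, the
#' same convention used when quoting rms levels of two-channel stimuli.
#'
#' @param track an [audio_track()].
#' @return a mono `audio_track`.
#' @export
to_mono <- function(track) {
  stopifnot(inherits(track, "audio_track"))
  if (ncol(track$samples) == 1) return(track)
  audio_track(rowMeans(track$samples), track$sample_rate, bpm = track$bpm)
}

#' Root-mean-square level of a track
#'
#' @param track an [audio_track()].
#' @return rms averaged over channels.
#' @export
track_rms <- function(track) {
  mean(apply(track$samples, 2, function(ch) sqrt(mean(ch^2))))
}

#' Peak-normalize a track
#'
#' Rescales so the maximum absolute sample equals `peak` (default 0.5, the
#' convention used for the parametric-modulation stimuli). The resulting rms
#' (averaged over channels) is attached as attribute `"rms"`.
#'
#' @param track an [audio_track()].
#' @param peak target peak amplitude.
#' @return the rescaled `audio_track` with attribute `rms`.
#' @export
peak_normalize <- function(track, peak = 0.5) {
  stopifnot(inherits(track, "audio_track"))
  mx <- max(abs(track$samples))
  if (mx == 0) abort("cannot peak-normalize silence", class = "ammod_invalid_input")
  out <- audio_track(track$samples * (peak / mx), track$sample_rate, bpm = track$bpm)
  attr(out, "rms") <- track_rms(out)
  out
}
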