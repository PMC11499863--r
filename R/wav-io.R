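#' Read a WAV file
#'
#' Reads RIFF/WAVE files containing 16- or 24-bit PCM or 32-bit IEEE float
#' samples. Samples are returned scaled to \[-1, 1\].
#'
#' @param path path to a `.wav` file.
#' @return an [audio_track()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort("not a RIFF file", class = "ammod_io_error")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort("not a WAVE file", class = "ammod_io_error")

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        n_channels = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        sample_rate = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, size = 4, endian = "little"),
        block_align = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
      extra <- sz - 16
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) abort("malformed WAV: missing fmt/data chunk", class = "ammod_io_error")

  nch <- fmt$n_channels
  if (fmt$format == 1 && fmt$bits == 16) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                 endian = "little", signed = TRUE) / 32768
  } else if (fmt$format == 1 && fmt$bits == 24) {
    n <- length(data_raw) %/% 3
    b <- matrix(as.integer(data_raw), nrow = 3)[, seq_len(n), drop = FALSE]
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else if (fmt$format == 3 && fmt$bits == 32) {
    x <- readBin(data_raw, "numeric", length(data_raw) / 4, size = 4, endian = "little")
  } else {
    abort(sprintf("unsupported WAV encoding (format %d, %d bit)", fmt$format, fmt$bits),
          class = "ammod_io_error")
  }
  audio_track(matrix(x, ncol = nch, byrow = TRUE), fmt$sample_rate)
}

#' Write a WAV file
#'
#' @param track an [audio_track()].
#' @param path output path.
#' @param bits 16 (PCM) or 32 (IEEE float, default).
#' @return `path`, invisibly.
#' @export
write_wav <- function(track, path, bits = 32) {
  stopifnot(inherits(track, "audio_track"), bits %in% c(16, 32))
  x <- t(track$samples) # interleave
  n_bytes <- length(x) * bits / 8
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(if (bits == 32) 3 else 1), con, size = 2, endian = "little")
  writeBin(as.integer(ncol(track$samples)), con, size = 2, endian = "little")
  writeBin(as.integer(track$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(track$sample_rate * ncol(track$samples) * bits / 8), con,
           size = 4, endian = "little")
  writeBin(as.integer(ncol(track$samples) * bits / 8), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  if (bits == 32) {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(pmax(pmin(round(x * 32767), 32767), -32768)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}
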