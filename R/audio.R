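#' Audio signal container
#'
#' A minimal mono audio container: a numeric sample vector in [-1, 1] plus a
#' sampling rate in Hz. The corpus recordings this pipeline targets are
#' single-channel far-field 16 kHz, 16-bit PCM.
#'
#' @param samples numeric vector of amplitudes (dimensionless, nominally [-1, 1]).
#' @param rate sampling rate in Hz (> 0).
#' @return an object of class `audio_signal`.
#' @export
audio_signal <- function(samples, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    dv_stop("dyadvox_input_error", "sampling rate must be a single positive number")
  samples <- as.numeric(samples)
  if (any(!is.finite(samples)))
    dv_stop("dyadvox_input_error", "audio samples must be finite")
  structure(list(samples = samples, rate = rate), class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.2f s)>\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param x an `audio_signal`.
#' @return duration in seconds.
#' @export
audio_duration <- function(x) length(x$samples) / x$rate

#' Read a PCM WAV file as a mono audio signal
#'
#' Reads 8/16/24/32-bit integer PCM and 32/64-bit float WAV. Multi-channel
#' input is downmixed to mono by averaging the channels; the sampling rate is
#' preserved.
#'
#' @param path path to a WAV file.
#' @return an `audio_signal`.
#' @export
load_audio <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    dv_stop("dyadvox_input_error", "cannot read audio file '%s': missing or empty", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    dv_stop("dyadvox_format_error", "'%s' is not a RIFF/WAV file", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    dv_stop("dyadvox_format_error", "'%s' is not a WAV file", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size + size %% 2L)
      u16 <- function(i) sum(as.integer(body[i:(i + 1L)]) * c(1, 256))
      u32 <- function(i) sum(as.numeric(body[i:(i + 3L)]) * c(1, 256, 65536, 16777216))
      fmt <- list(code = u16(1L), channels = u16(3L), rate = u32(5L), bits = u16(15L))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L == 1L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    dv_stop("dyadvox_format_error", "'%s': missing fmt or data chunk", path)
  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes
  if (fmt$code == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n, 2L, signed = TRUE, endian = "little") / 32768
  } else if (fmt$code == 1L && fmt$bits == 8L) {
    x <- (readBin(data_raw, "integer", n, 1L, signed = FALSE) - 128) / 128
  } else if (fmt$code == 1L && fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw[seq_len(n * 3L)]), nrow = 3L)
    v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else if (fmt$code == 1L && fmt$bits == 32L) {
    x <- readBin(data_raw, "integer", n, 4L, signed = TRUE, endian = "little") / 2147483648
  } else if (fmt$code == 3L && fmt$bits %in% c(32L, 64L)) {
    x <- readBin(data_raw, "numeric", n, bytes, endian = "little")
  } else {
    dv_stop("dyadvox_format_error",
            "'%s': unsupported WAV encoding (format %d, %d bit)", path, fmt$code, fmt$bits)
  }
  if (fmt$channels > 1L) {
    nf <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(nf * fmt$channels)], nrow = fmt$channels))
  }
  audio_signal(x, fmt$rate)
}

#' Write a mono audio signal as 16-bit PCM WAV
#'
#' @param audio an `audio_signal`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_audio <- function(audio, path) {
  stopifnot(inherits(audio, "audio_signal"))
  x <- pmin(pmax(audio$samples, -1), 32767 / 32768)
  pcm <- as.integer(round(x * 32768))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")                  # PCM
  writeBin(1L, con, 2L, endian = "little")                  # mono
  writeBin(as.integer(audio$rate), con, 4L, endian = "little")
  writeBin(as.integer(audio$rate * 2L), con, 4L, endian = "little")
  writeBin(2L, con, 2L, endian = "little")
  writeBin(16L, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4L, endian = "little")
  writeBin(pcm, con, 2L, endian = "little")
  invisible(path)
}
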