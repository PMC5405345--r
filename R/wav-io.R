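#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' Writes a canonical RIFF/WAVE file (PCM, 16-bit little-endian, single
#' channel). Samples are expected in `[-1, 1]`; values outside that range are
#' clipped before quantization.
#'
#' @param samples Numeric vector of samples in `[-1, 1]`.
#' @param path Output file path.
#' @param rate_hz Sampling rate in Hz (default 44100).
#' @return `path`, invisibly.
#' @seealso [read_wav()]
#' @export
write_wav <- function(samples, path, rate_hz = 44100L) {
  stopifnot(is.numeric(samples), length(samples) > 0L)
  x <- pmax(-1, pmin(1, samples))
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(rate_hz) * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' Reads RIFF/WAVE PCM data. Stereo files are downmixed to mono by summing
#' the two channels (the convention used throughout this package for feature
#' extraction); the summed signal is rescaled to peak at most 1.
#'
#' @param path Path to a `.wav` file (PCM, 16-bit).
#' @return A list with `samples` (numeric, in `[-1, 1]`) and `rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1L, size = 4, endian = "little")
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  rate_hz <- NA_integer_; n_channels <- NA_integer_; bits <- NA_integer_
  samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1L, size = 2, endian = "little")
      if (fmt != 1L) stop("only PCM WAV is supported")
      n_channels <- readBin(con, "integer", 1L, size = 2, endian = "little")
      rate_hz <- readBin(con, "integer", 1L, size = 4, endian = "little")
      readBin(con, "integer", 1L, size = 4, endian = "little")
      readBin(con, "integer", 1L, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1L, size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit PCM is supported")
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", size %/% 2L, size = 2, endian = "little")
      samples <- pcm / 32767
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (!is.na(n_channels) && n_channels == 2L) {
    samples <- samples[seq(1L, length(samples), by = 2L)] +
      samples[seq(2L, length(samples), by = 2L)]
    peak <- max(abs(samples))
    if (peak > 1) samples <- samples / peak
  }
  list(samples = samples, rate_hz = rate_hz)
}
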