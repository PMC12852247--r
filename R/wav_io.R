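#' Read a RIFF PCM WAV file
#'
#' Minimal reader for uncompressed 16-bit (or 8/32-bit integer) PCM WAV.
#' Chunks other than `fmt ` and `data` are skipped. Samples are returned on
#' the full-scale-relative \[-1, 1\] scale.
#'
#' @param path Path to a `.wav` file.
#' @param channel Channel to return for multi-channel files (1-based). The
#'   recordings this mirrors carry the signal on channel 1 and a voice
#'   annotation track on channel 2.
#' @return List with `samples` (numeric vector) and `sample_rate` (Hz).
#' @export
read_wav <- function(path, channel = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = sum(as.integer(raw[1:2]) * c(1, 256)),
        n_channels   = sum(as.integer(raw[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(raw[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk")
      bytes <- fmt$bits / 8
      n <- size %/% bytes
      samples <- readBin(con, "integer", n, bytes, signed = fmt$bits > 8,
                         endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
  if (is.null(fmt) || is.null(samples)) stop("missing fmt/data chunk: ", path)
  if (fmt$audio_format != 1) stop("only PCM WAV is supported")
  if (channel < 1 || channel > fmt$n_channels) stop("invalid channel")
  if (fmt$n_channels > 1)
    samples <- samples[seq(channel, length(samples), by = fmt$n_channels)]
  scale <- if (fmt$bits == 8) { samples <- samples - 128; 128 } else 2^(fmt$bits - 1)
  list(samples = samples / scale, sample_rate = fmt$sample_rate)
}

#' Write a mono or stereo 16-bit PCM WAV file
#'
#' @param samples Numeric vector (mono) or matrix with one column per
#'   channel, on the \[-1, 1\] scale; values outside are clipped.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  n_ch <- ncol(samples)
  x <- t(samples) # interleave channels
  pcm <- as.integer(round(pmax(pmin(as.numeric(x), 1), -1) * 32767))
  data_size <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * n_ch * 2L, con, size = 4, endian = "little")
  writeBin(n_ch * 2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
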