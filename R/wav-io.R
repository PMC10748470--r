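#' Read and write 16-bit PCM WAV files
#'
#' Minimal RIFF/WAVE codec for the pipeline's native format: PCM, 16-bit,
#' 44.1 kHz, mono or stereo. `write_wav()` clamps samples to `[-1, 1]` and
#' quantises to 16-bit integers; `read_wav()` returns amplitudes rescaled to
#' `[-1, 1]`, one column per channel.
#'
#' @param samples Numeric vector (mono) or matrix with one column per channel,
#'   amplitudes in `[-1, 1]`.
#' @param path File path.
#' @param sample_rate Samples per second (default 44100).
#' @return `read_wav()`: a list with `samples` (matrix, one column per
#'   channel), `sample_rate`, `bits` and `n_channels`. `write_wav()`:
#'   `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".wav")
#' write_wav(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 44100)), f)
#' w <- read_wav(f)
#' w$sample_rate
#' @export
write_wav <- function(samples, path, sample_rate = 44100) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  n_ch <- ncol(samples)
  x <- t(samples)                       # interleave channels
  x <- pmin(pmax(as.numeric(x), -1), 1)
  pcm <- as.integer(round(x * 32767))
  data_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")            # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")             # PCM
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * n_ch * 2L), con, size = 4,
           endian = "little")                                # byte rate
  writeBin(as.integer(n_ch * 2L), con, size = 2, endian = "little") # block align
  writeBin(16L, con, size = 2, endian = "little")            # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    stop_invalid("WAV file does not exist: ", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop_invalid("not a RIFF/WAVE file: ", path)
  }
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) {
      stop_invalid("malformed WAV (no data chunk): ", path)
    }
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, integer(), size = 2, endian = "little"),
        n_channels   = readBin(con, integer(), size = 2, endian = "little"),
        sample_rate  = readBin(con, integer(), size = 4, endian = "little"),
        byte_rate    = readBin(con, integer(), size = 4, endian = "little"),
        block_align  = readBin(con, integer(), size = 2, endian = "little"),
        bits         = readBin(con, integer(), size = 2, endian = "little")
      )
      if (size > 16) readBin(con, raw(), n = size - 16)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop_invalid("malformed WAV (data before fmt): ", path)
      if (fmt$audio_format != 1L || fmt$bits != 16L) {
        stop_invalid("unsupported WAV codec (need 16-bit PCM): ", path)
      }
      pcm <- readBin(con, integer(), n = size / 2, size = 2, signed = TRUE,
                     endian = "little")
      samples <- matrix(pcm / 32767, ncol = fmt$n_channels, byrow = TRUE)
      return(list(samples = samples, sample_rate = fmt$sample_rate,
                  bits = fmt$bits, n_channels = fmt$n_channels))
    } else {
      readBin(con, raw(), n = size)
    }
  }
}
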