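#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the vocoder: 16-bit integer PCM or
#' 32-bit IEEE float, single channel.  Samples are returned on the
#' [-1, 1] scale.
#'
#' @param path WAV file path.
#' @return List with \code{samples} (numeric vector) and
#'   \code{sample_rate} (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) .stopf("'%s' is not a RIFF file", path)
  readBin(con, "integer", 1, 4, endian = "little")       # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) .stopf("'%s' is not a WAVE file", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little",
                               signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little"),
        sample_rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little"),
        bits = readBin(con, "integer", 1, 2, endian = "little"))
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) .stopf("malformed WAV file '%s'", path)
  if (fmt$channels != 1) .stopf("only mono WAV is supported (%d channels)",
                                fmt$channels)
  samples <- if (fmt$audio_format == 1 && fmt$bits == 16) {
    readBin(data_raw, "integer", length(data_raw) / 2, 2, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$audio_format == 3 && fmt$bits == 32) {
    readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
  } else {
    .stopf("unsupported WAV encoding (format %d, %d bit)",
           fmt$audio_format, fmt$bits)
  }
  list(samples = samples, sample_rate = fmt$sample_rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples Numeric vector on the [-1, 1] scale; values outside are
#'   clipped.
#' @param path Output path.
#' @param sample_rate Sampling rate in Hz.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = 16000) {
  pcm <- as.integer(pmin(round(pmin(pmax(samples, -1), 1) * 32768), 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n_bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                 # PCM
  writeBin(1L, con, 2, endian = "little")                 # mono
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
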