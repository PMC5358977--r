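#' Minimal mono PCM WAV reader / writer
#'
#' Reads and writes uncompressed 16-bit PCM mono WAV files (the native
#' format of the recording systems this package targets, e.g. 250 kHz /
#' 16-bit). Samples are scaled to `[-1, 1]` full scale.
#'
#' @param path file path.
#' @return `read_wav()`: numeric waveform with attribute `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  sample_rate <- NULL; bits <- NULL; channels <- NULL; wav <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 1, 2, endian = "little"))
      bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (id == "data") {
      if (bits != 16) stop("only 16-bit PCM WAV is supported")
      wav <- readBin(con, "integer", size / 2, 2, endian = "little") / 32768
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(wav)) stop("no data chunk found in ", path)
  if (!is.null(channels) && channels != 1) stop("only mono WAV is supported")
  attr(wav, "sample_rate") <- sample_rate
  wav
}

#' @rdname read_wav
#' @param wav numeric waveform in `[-1, 1]`.
#' @param sample_rate sampling rate, Hz; defaults to the waveform's
#'   `sample_rate` attribute.
#' @export
write_wav <- function(wav, path, sample_rate = attr(wav, "sample_rate")) {
  if (is.null(sample_rate)) stop("sample_rate required")
  pcm <- as.integer(pmax(pmin(round(wav * 32767), 32767), -32768))
  n <- length(pcm)
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, 4, endian = "little")
  writeBin(as.integer(c(1, 1)), con, 2, endian = "little")   # PCM, mono
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, 4, endian = "little")
  writeBin(as.integer(c(2, 16)), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
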