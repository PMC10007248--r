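#' Write a mono waveform as a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer for the telephone-bandwidth recordings used in
#' this package: mono, 16-bit signed PCM. Samples outside `[-1, 1]` are
#' clipped.
#'
#' @param x numeric vector of samples in `[-1, 1]`.
#' @param path output file path.
#' @param sample_rate sampling rate in Hz (default 8000).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, sample_rate = 8000L) {
  stopifnot(is.numeric(x), length(x) > 0, all(is.finite(x)))
  pcm <- as.integer(round(pmin(pmax(x, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")            # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")             # PCM
  writeBin(1L, con, size = 2, endian = "little")             # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")             # block align
  writeBin(16L, con, size = 2, endian = "little")            # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Counterpart of [write_wav()]. Only uncompressed mono 16-bit PCM is
#' supported, which is the format this package emits.
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric in `[-1, 1]`) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path)
  }
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) {
        stop("only mono PCM WAV is supported")
      }
      sample_rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")   # byte rate
      ba <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (ba[2] != 16L) stop("only 16-bit PCM WAV is supported")
      if (size > 16) readBin(con, "raw", n = size - 16L)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", n = size %/% 2L, size = 2,
                     signed = TRUE, endian = "little")
      return(list(samples = pcm / 32767, sample_rate = sample_rate))
    } else {
      readBin(con, "raw", n = size)
    }
  }
}
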