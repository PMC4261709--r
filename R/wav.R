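# Minimal mono PCM16 RIFF/WAVE reader and writer. No audio package is a
# declared dependency; the acquisition dialect stores plain 16-bit mono
# PCM, which these two functions cover completely.

#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' Samples are clipped to \[-1, 1\] and quantised to 16-bit integers, so a
#' read-back differs from the input by at most one quantisation step
#' (1/32767).
#'
#' @param samples numeric vector in \[-1, 1\].
#' @param rate sample rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  stopifnot(is.numeric(samples), length(rate) == 1L, rate > 0)
  con <- tryCatch(file(path, "wb"), condition = function(e)
    abort_dyadscope("IOFailure", sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con))
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  n <- length(pcm)
  data_bytes <- 2L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate) * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path file path.
#' @return list with `samples` (numeric in \[-1, 1\]) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  if (!file.exists(path))
    abort_dyadscope("BundleIncomplete", sprintf("WAV file '%s' not found", path))
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    abort_dyadscope("ParseError", sprintf("'%s' is not a RIFF/WAVE file", path))
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt != 1L || channels != 1L || bits != 16L)
        abort_dyadscope("ParseError",
          sprintf("'%s': only mono 16-bit PCM supported", path))
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size %/% 2L, size = 2,
                         endian = "little", signed = TRUE) / 32767
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  if (is.null(rate) || is.null(samples))
    abort_dyadscope("ParseError", sprintf("'%s': missing fmt or data chunk", path))
  list(samples = samples, rate = rate)
}
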