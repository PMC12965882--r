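# Minimal mono PCM16 WAV reader/writer (RIFF), 16 kHz default.

#' Write a mono waveform to a 16-bit PCM WAV file
#' @param wave Numeric samples in `[-1, 1]` (clipped otherwise).
#' @param path Output file path.
#' @param fs Sampling rate, Hz.
#' @export
write_wav <- function(wave, path, fs = NV_FS_AUDIO) {
  pcm <- as.integer(round(pmin(pmax(wave, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#' @param path File path.
#' @return List with `wave` (samples in `[-1, 1]`) and `fs`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("read_wav: not a RIFF file")
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("read_wav: not a WAVE file")
  fs <- NULL; wave <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("read_wav: only mono PCM supported")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      bits <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (bits[2] != 16L) stop("read_wav: only 16-bit PCM supported")
    } else if (id == "data") {
      wave <- readBin(con, "integer", sz %/% 2L, size = 2, signed = TRUE,
                      endian = "little") / 32767
      break
    } else {
      readBin(con, "raw", sz)
    }
  }
  if (is.null(wave)) stop("read_wav: no data chunk found")
  list(wave = wave, fs = fs)
}
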