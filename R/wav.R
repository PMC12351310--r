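# Minimal RIFF/WAVE I/O. Supports the two encodings the pipeline emits:
# 16-bit PCM and 32-bit IEEE float, mono or multichannel (mono used here).

#' Write a waveform to a RIFF WAV file
#'
#' @param wave Numeric vector (or channel-by-sample matrix) in `[-1, 1]`.
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, sample_rate, bits = 16L) {
  if (is.matrix(wave)) { n_chan <- nrow(wave); samples <- as.vector(wave) }
  else { n_chan <- 1L; samples <- as.numeric(wave) }
  stopifnot(all(is.finite(samples)), sample_rate > 0, bits %in% c(16L, 32L))
  n_frames <- length(samples) / n_chan
  fmt_code <- if (bits == 16L) 1L else 3L # PCM vs IEEE float
  block_align <- n_chan * bits / 8L
  data_bytes <- as.integer(n_frames * block_align)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(as.integer(n_chan), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * block_align), con, size = 4, endian = "little")
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  if (bits == 16L) {
    x <- pmax(-1, pmin(1, samples))
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(samples, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a RIFF WAV file
#'
#' @param path WAV file path (16-bit PCM or 32-bit float).
#' @return List with `wave` (numeric vector, mono-mixed if multichannel;
#'   range `[-1, 1]` for PCM) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        code = readBin(con, integer(), size = 2, endian = "little"),
        n_chan = readBin(con, integer(), size = 2, endian = "little"),
        rate = readBin(con, integer(), size = 4, endian = "little"),
        byte_rate = readBin(con, integer(), size = 4, endian = "little"),
        block = readBin(con, integer(), size = 2, endian = "little"),
        bits = readBin(con, integer(), size = 2, endian = "little"))
      if (sz > 16) readBin(con, raw(), n = sz - 16L)
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data before fmt")
      if (fmt$bits == 16L) {
        samples <- readBin(con, integer(), n = sz / 2L, size = 2,
                           signed = TRUE, endian = "little") / 32767
      } else if (fmt$bits == 32L && fmt$code == 3L) {
        samples <- readBin(con, numeric(), n = sz / 4L, size = 4,
                           endian = "little")
      } else stop("unsupported WAV encoding (", fmt$bits, " bit, code ", fmt$code, ")")
    } else {
      readBin(con, raw(), n = sz + sz %% 2L)
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk in ", path)
  if (fmt$n_chan > 1L) {
    samples <- colMeans(matrix(samples, nrow = fmt$n_chan))
  }
  list(wave = samples, sample_rate = fmt$rate)
}
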