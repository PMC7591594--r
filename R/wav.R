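#' Minimal WAV reading and writing for respiratory traces
#'
#' Respiratory signals exported from acquisition software commonly travel
#' as single-channel WAV files. These helpers cover the formats that
#' matter for that use: uncompressed PCM (16- or 32-bit integer) and IEEE
#' float (32-bit), mono. Integer samples are scaled to `[-1, 1]`.
#'
#' @param path file path.
#' @return `read_wav()`: a list with `samples` (numeric) and
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file", call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file", call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2,
                               endian = "little", signed = FALSE),
        n_channels = readBin(fmt_raw[3:4], "integer", 1, 2,
                             endian = "little", signed = FALSE),
        sample_rate = readBin(fmt_raw[5:8], "integer", 1, 4,
                              endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, 2,
                       endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV: missing fmt or data chunk", call. = FALSE)
  }
  if (fmt$n_channels != 1L) {
    stop("only mono WAV traces are supported", call. = FALSE)
  }
  n <- length(data_raw) %/% (fmt$bits %/% 8L)
  samples <- if (fmt$audio_format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "double", n, 4, endian = "little")
  } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", n, 2, endian = "little") / 32768
  } else if (fmt$audio_format == 1L && fmt$bits == 32L) {
    readBin(data_raw, "integer", n, 4, endian = "little") / 2147483648
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bit)",
                 fmt$audio_format, fmt$bits), call. = FALSE)
  }
  list(samples = samples, sample_rate = fmt$sample_rate)
}

#' @rdname read_wav
#' @param samples numeric vector.
#' @param sample_rate sampling rate in Hz.
#' @param bits 32 (IEEE float, default: lossless for analysis signals) or
#'   16 (PCM; samples must lie in `[-1, 1]`).
#' @export
write_wav <- function(samples, sample_rate, path, bits = 32) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  bytes <- bits %/% 8L
  data_size <- n * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(if (bits == 32) 3L else 1L), con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes), con, 4, endian = "little")
  writeBin(as.integer(bytes), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 32) {
    writeBin(as.numeric(samples), con, 4, endian = "little")
  } else {
    if (any(abs(samples) > 1)) {
      stop("16-bit PCM needs samples in [-1, 1]", call. = FALSE)
    }
    writeBin(as.integer(round(samples * 32767)), con, 2, endian = "little")
  }
  invisible(path)
}
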