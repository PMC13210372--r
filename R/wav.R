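# Minimal RIFF WAV reader/writer for mono 16 kHz clips.
# Supports PCM 16-bit and IEEE float32; that is all the bundle format needs.

#' Read a mono WAV file
#'
#' @param path file path
#' @return list with `samples` (numeric in \[-1, 1\]) and `sample_rate`
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) np_stop("np_format_error", "not a RIFF file: %s", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) np_stop("np_format_error", "not a WAVE file: %s", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      audio_format <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      n_channels <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      sample_rate <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little")) # byte rate
      invisible(readBin(con, "integer", 1, 2, endian = "little")) # block align
      bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      if (size > 16) invisible(readBin(con, "raw", size - 16))
      fmt <- list(format = audio_format, channels = n_channels,
                  rate = sample_rate, bits = bits)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) np_stop("np_format_error", "WAV data chunk before fmt chunk")
      if (fmt$channels != 1L) np_stop("np_format_error", "only mono WAV supported")
      if (fmt$format == 1L && fmt$bits == 16L) {
        raw16 <- readBin(con, "integer", size / 2, 2, endian = "little", signed = TRUE)
        samples <- raw16 / 32768
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "double", size / 4, 4, endian = "little")
      } else {
        np_stop("np_format_error", "unsupported WAV encoding (format %d, %d bits)",
                fmt$format, fmt$bits)
      }
      if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) np_stop("np_format_error", "WAV file has no data chunk: %s", path)
  list(samples = as.numeric(samples), sample_rate = fmt$rate)
}

#' Write a mono WAV file
#'
#' @param samples numeric vector in \[-1, 1\]
#' @param path output path
#' @param sample_rate sampling rate in Hz
#' @param bits 32 (IEEE float, default: lossless to single precision) or 16 (PCM)
#' @return `path`, invisibly
#' @export
write_wav <- function(samples, path, sample_rate = 16000L, bits = 32L) {
  stopifnot(bits %in% c(16L, 32L))
  samples <- clamp(as.numeric(samples), -1, 1)
  n <- length(samples)
  bytes_per <- bits / 8L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(if (bits == 16L) 1L else 3L, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16L) {
    writeBin(as.integer(round(samples * 32767)), con, 2, endian = "little")
  } else {
    writeBin(samples, con, 4, endian = "little")
  }
  invisible(path)
}
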