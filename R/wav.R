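# Minimal RIFF/WAVE reader and writer (mono or multi-channel PCM).
# Supports 16-bit integer PCM and 32-bit IEEE float, which covers the
# stimulus audio this pipeline consumes and renders.

#' Read a WAV file
#'
#' @param path path to a RIFF/WAVE file (16-bit PCM or 32-bit float).
#' @param to_mono average channels down to mono (default TRUE; the analysis
#'   operates on mono audio).
#' @return list with `samples` (numeric in \[-1, 1\]), `rate` (Hz),
#'   `n_channels` as read from the header.
#' @export
read_wav <- function(path, to_mono = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_ds("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_ds("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        n_channels   = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits         = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      )
      extra <- size - 16L
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L == 1L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop_ds("missing fmt/data chunk in ", path)

  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n = length(data_raw) / 2L, size = 2L,
                 endian = "little", signed = TRUE) / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "numeric", n = length(data_raw) / 4L, size = 4L,
                 endian = "little")
  } else {
    stop_ds("unsupported WAV encoding (format ", fmt$audio_format,
            ", ", fmt$bits, " bits)")
  }
  nc <- fmt$n_channels
  if (nc > 1L) {
    x <- matrix(x, nrow = nc)
    samples <- if (to_mono) colMeans(x) else x
  } else {
    samples <- x
  }
  list(samples = samples, rate = fmt$sample_rate, n_channels = nc)
}

#' Write a mono WAV file
#'
#' @param samples numeric vector in \[-1, 1\] (values are clipped).
#' @param rate sampling rate, Hz.
#' @param path output path.
#' @param bits 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path, bits = 16L) {
  if (!bits %in% c(16L, 32L)) stop_ds("bits must be 16 or 32")
  samples <- pmin(1, pmax(-1, samples))
  n <- length(samples)
  bytes_per <- bits / 8L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(if (bits == 16L) 1L else 3L, con, size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(as.integer(rate), con, size = 4L, endian = "little")
  writeBin(as.integer(rate * bytes_per), con, size = 4L, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2L, endian = "little")
  writeBin(as.integer(bits), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (bits == 16L) {
    writeBin(as.integer(round(samples * 32767)), con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, size = 4L, endian = "little")
  }
  invisible(path)
}
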