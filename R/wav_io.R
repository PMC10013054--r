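#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed integer PCM (16- or 24-bit) and
#' 32-bit IEEE float. Multichannel input is averaged to mono; samples are
#' rescaled to \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @return A [sound_wave].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        n_channels = readBin(fmt_raw[3:4], "integer", 1, 2,
                             signed = FALSE, endian = "little"),
        sample_rate = readBin(fmt_raw[5:8], "integer", 1, 4,
                              endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, 2,
                       signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("missing fmt or data chunk in WAV file: ", path)
  if (!fmt$audio_format %in% c(1L, 3L))
    stop("unsupported WAV encoding (format tag ", fmt$audio_format,
         "); only integer PCM and IEEE float are supported")

  if (fmt$audio_format == 3L) {
    if (fmt$bits != 32) stop("only 32-bit float WAV is supported")
    x <- readBin(data_raw, "numeric", length(data_raw) / 4, 4,
                 endian = "little")
  } else if (fmt$bits == 16) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$bits == 24) {
    n <- length(data_raw) / 3
    m <- matrix(as.integer(data_raw), nrow = 3)
    x <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
    x <- ifelse(x >= 8388608, x - 16777216, x) / 8388608
  } else {
    stop("unsupported PCM bit depth: ", fmt$bits)
  }

  if (fmt$n_channels > 1) {
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  peak <- max(abs(x))
  if (peak > 1) x <- x / peak
  sound_wave(x, fmt$sample_rate)
}

#' Write a sound wave to a 16-bit PCM WAV file
#'
#' @param wave A [sound_wave]; samples are clipped to \[-1, 1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path) {
  stopifnot(inherits(wave, "sound_wave"))
  x <- pmax(-1, pmin(1, wave$samples))
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")          # PCM, mono
  writeBin(as.integer(wave$sample_rate), con, 4, endian = "little")
  writeBin(as.integer(wave$sample_rate * 2), con, 4, endian = "little")
  writeBin(c(2L, 16L), con, 2, endian = "little")          # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
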