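#' Audio signal container
#'
#' @param samples Numeric vector of amplitudes, nominally in [-1, 1].
#' @param sample_rate Sampling rate in Hz (positive integer).
#' @return An object of class `audio_signal`.
#' @export
audio_signal <- function(samples, sample_rate) {
  if (length(samples) == 0L) stop("samples must be non-empty", call. = FALSE)
  if (!is.numeric(samples) || anyNA(samples) || any(!is.finite(samples))) {
    stop("samples must be finite numeric", call. = FALSE)
  }
  sample_rate <- as.integer(sample_rate)
  if (is.na(sample_rate) || sample_rate <= 0L) {
    stop("sample_rate must be a positive integer", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %d Hz (%.3f s), peak %.3f>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, max(abs(x$samples))))
  invisible(x)
}

#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader supporting 16- and 24-bit integer PCM and
#' 32-bit IEEE float, the formats produced by common recorders and by
#' [write_wav()]. Stereo files are averaged to mono with a warning.
#' Integer samples are scaled to [-1, 1].
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      u16 <- function(off) sum(as.integer(body[off + 1:2]) * c(1, 256))
      u32 <- function(off) sum(as.integer(body[off + 1:4]) * 256^(0:3))
      fmt <- list(audio_format = u16(0), n_channels = u16(2),
                  sample_rate = u32(4), bits = u16(14))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz)  # skip unknown chunk
    }
    if (sz %% 2 == 1) readBin(con, "raw", 1)  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("missing fmt/data chunk in ", path, call. = FALSE)
  }

  bytes <- fmt$bits / 8
  n <- length(data_raw) %/% bytes
  x <- if (fmt$audio_format == 1 && fmt$bits == 16) {
    readBin(data_raw, "integer", n, size = 2, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$audio_format == 1 && fmt$bits == 24) {
    m <- matrix(as.integer(data_raw[seq_len(n * 3)]), nrow = 3)
    v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else if (fmt$audio_format == 3 && fmt$bits == 32) {
    readBin(data_raw, "double", n, size = 4, endian = "little")
  } else {
    stop(sprintf("unsupported WAV format (format=%d, bits=%d)",
                 fmt$audio_format, fmt$bits), call. = FALSE)
  }

  if (fmt$n_channels > 1L) {
    warning("averaging ", fmt$n_channels, " channels to mono", call. = FALSE)
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  peak <- max(abs(x))
  if (peak > 1) x <- x / peak
  audio_signal(x, fmt$sample_rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param signal An [audio_signal()] (or numeric vector with `sample_rate`).
#' @param path Output path.
#' @param sample_rate Required if `signal` is a bare numeric vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, sample_rate = NULL) {
  if (!inherits(signal, "audio_signal")) {
    signal <- audio_signal(signal, sample_rate)
  }
  x <- pmax(pmin(signal$samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(signal$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(signal$sample_rate * 2L), con, size = 4,
           endian = "little")                       # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
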