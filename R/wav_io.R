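#' Read a RIFF WAV file (PCM 16-bit)
#'
#' Minimal RIFF/WAVE reader for the PCM formats this pipeline consumes.
#' Chunks other than \code{fmt } and \code{data} are skipped. Samples are
#' returned as a numeric matrix (one column per channel) scaled to
#' [-1, 1) by the 16-bit full scale (32768).
#'
#' @param path Path to a \code{.wav} file.
#' @return A list with \code{samples} (numeric matrix, n x channels),
#'   \code{rate} (Hz), \code{bits} (bits per sample).
#' @keywords internal
read_wav <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read WAV file (no such file): ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))

  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) {
    stop("not a RIFF WAV file: ", path, call. = FALSE)
  }
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop("not a WAVE file: ", path, call. = FALSE)
  }

  rate <- NULL; n_channels <- NULL; bits <- NULL; raw_data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(sz) == 0) break
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      audio_format <- fmt[1]; n_channels <- fmt[2]
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little")) # byte rate
      invisible(readBin(con, "integer", 1, size = 2, endian = "little")) # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
      if (audio_format != 1L) {
        stop("unsupported WAV encoding (only PCM is supported): ", path,
             call. = FALSE)
      }
    } else if (identical(id, "data")) {
      raw_data <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(raw_data) && !is.null(rate)) break
  }

  if (is.null(rate) || is.null(raw_data)) {
    stop("corrupt or truncated WAV file: ", path, call. = FALSE)
  }
  if (!bits %in% c(8L, 16L)) {
    stop("unsupported PCM bit depth (", bits, "): ", path, call. = FALSE)
  }
  if (length(raw_data) == 0) {
    stop("zero-length audio in WAV file: ", path, call. = FALSE)
  }

  if (bits == 16L) {
    vals <- readBin(raw_data, "integer", length(raw_data) / 2,
                    size = 2, signed = TRUE, endian = "little") / 32768
  } else {
    vals <- (readBin(raw_data, "integer", length(raw_data),
                     size = 1, signed = FALSE) - 128) / 128
  }
  n_frames <- length(vals) %/% n_channels
  samples <- matrix(vals[seq_len(n_frames * n_channels)],
                    ncol = n_channels, byrow = TRUE)
  list(samples = samples, rate = rate, bits = bits)
}

#' Write a mono or multichannel signal as PCM 16-bit WAV
#'
#' @param samples Numeric vector (mono) or matrix (n x channels) in [-1, 1].
#' @param rate Sample rate in Hz.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @keywords internal
write_wav <- function(samples, rate, path) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  n_channels <- ncol(samples)
  x <- t(samples)                       # interleave channels
  q <- as.integer(pmax(-32768, pmin(32767, round(as.numeric(x) * 32768))))
  data_size <- length(q) * 2L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(as.integer(n_channels), con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * n_channels * 2L), con, size = 4, endian = "little")
  writeBin(as.integer(n_channels * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}
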