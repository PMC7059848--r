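#' Gaussian-window log spectrogram
#'
#' Short-time Fourier magnitude with a Gaussian window whose *spectral*
#' standard deviation is \code{window_bandwidth} Hz (so the temporal
#' standard deviation is 1/(2*pi*window_bandwidth) seconds). Magnitudes
#' are expressed in dB relative to the grid maximum and clipped at
#' \code{-floor_db} dB below it, so all values are finite.
#'
#' The hop is \code{round(rate * frame_step)} samples; the realized frame
#' step (\code{hop/rate}) is stored and used by all downstream axis
#' computations, so modulation axes are exact even when \code{rate *
#' frame_step} is not an integer.
#'
#' @param sig A standardized \code{audio_signal}.
#' @param window_bandwidth Gaussian spectral bandwidth in Hz. Default 50.
#' @param frame_step Requested hop between frames in seconds. Default 1 ms.
#' @param floor_db Dynamic range below the maximum, in dB (positive number).
#'   Default 80.
#' @return An object of class \code{spectrogram}: \code{values} (dB matrix,
#'   time frames x frequency bins), \code{frame_step} (s, realized),
#'   \code{freq_step} (Hz), \code{freqs}, \code{window_bandwidth},
#'   \code{floor_db}, \code{rate}.
#' @export
compute_spectrogram <- function(sig, window_bandwidth = 50,
                                frame_step = 0.001, floor_db = 80) {
  stopifnot(inherits(sig, "audio_signal"))
  if (window_bandwidth <= 0) stop("window_bandwidth must be > 0", call. = FALSE)
  if (frame_step <= 0) stop("frame_step must be > 0", call. = FALSE)
  rate <- sig$rate
  x <- sig$samples

  sigma_t <- 1 / (2 * pi * window_bandwidth)     # seconds
  sigma_n <- sigma_t * rate                      # samples
  # truncate at 5 sigma: truncation sidelobes ~ -108 dB, below the floor
  half <- ceiling(5 * sigma_n)
  win_len <- 2L * half + 1L
  if (length(x) < win_len) {
    stop("signal shorter than one analysis window (",
         sprintf("%.0f", win_len), " samples needed)", call. = FALSE)
  }
  win <- exp(-0.5 * ((seq_len(win_len) - half - 1) / sigma_n)^2)
  nfft <- 2^ceiling(log2(win_len))

  hop <- max(1L, round(rate * frame_step))
  n_frames <- (length(x) - win_len) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop

  frames <- matrix(0, nrow = nfft, ncol = n_frames)
  ii <- seq_len(win_len)
  for (f in seq_len(n_frames)) {
    frames[ii, f] <- x[starts[f] + ii] * win
  }
  mag <- abs(stats::mvfft(frames))[seq_len(nfft / 2 + 1), , drop = FALSE]

  mx <- max(mag)
  if (mx == 0) stop("all-zero signal: empty spectrogram", call. = FALSE)
  db <- 20 * log10(pmax(mag, mx * 10^(-abs(floor_db) / 20)) / mx)

  structure(list(
    values = t(db),                       # frames x freq bins
    frame_step = hop / rate,
    freq_step = rate / nfft,
    freqs = (seq_len(nfft / 2 + 1) - 1) * rate / nfft,
    window_bandwidth = window_bandwidth,
    floor_db = abs(floor_db),
    rate = rate
  ), class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(
    "<spectrogram> %d frames x %d bins; frame_step %.4g ms, freq_step %.4g Hz, bw %g Hz\n",
    nrow(x$values), ncol(x$values), x$frame_step * 1e3, x$freq_step,
    x$window_bandwidth))
  invisible(x)
}
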