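#' Speech modulation spectrum (2-D Fourier decomposition of the spectrogram)
#'
#' The log-amplitude spectrogram is cut into non-overlapping segments of
#' \code{segment_s} seconds. Each segment has its grand mean (over all dB
#' values) subtracted, is transformed with a 2-D FFT, and the power
#' \eqn{|F|^2 / (n_t n_f)} is averaged across segments. With this scaling
#' the total power of a segment over the full (uncropped) modulation grid
#' equals the sum of squared deviations of its dB values (Parseval).
#'
#' Axes: temporal modulation \eqn{\omega_t} in Hz (negative = up-sweeps,
#' positive = down-sweeps), spectral modulation \eqn{\omega_f} in
#' cycles/kHz. Because the spectrogram is real, the full 2-D transform has
#' point symmetry \eqn{P(-\omega_t, -\omega_f) = P(\omega_t, \omega_f)};
#' the grid is folded to \eqn{\omega_f \ge 0} with both \eqn{\omega_t}
#' half-planes retained, then cropped to
#' \eqn{[-tm\_max, tm\_max] \times [0, sm\_max]}.
#'
#' The grid shape depends only on the analysis parameters (segment length,
#' frame step, frequency step, crop bounds) -- never on recording duration
#' -- so pixel areas are comparable across recordings analyzed with the
#' same configuration.
#'
#' @param spec A \code{spectrogram}.
#' @param segment_s Segment length in seconds. Default 1 (so the temporal
#'   modulation step is ~1 Hz). A trailing remainder shorter than one
#'   segment is discarded.
#' @param tm_max Temporal-modulation crop bound in Hz. Default 100.
#' @param sm_max Spectral-modulation crop bound in cycles/kHz. Default 10.
#' @return An object of class \code{modulation_spectrum}: \code{power}
#'   (matrix, temporal x spectral modulation), \code{tm_axis} (Hz),
#'   \code{sm_axis} (cycles/kHz), \code{tm_step}, \code{sm_step},
#'   \code{tm_max}, \code{sm_max}, \code{n_segments}, \code{normalized}
#'   (FALSE), \code{total_power_uncropped} (per-segment mean, for energy
#'   accounting), and \code{grid_meta} (window/step parameters).
#' @export
compute_mps <- function(spec, segment_s = 1, tm_max = 100, sm_max = 10) {
  stopifnot(inherits(spec, "spectrogram"))
  n_t <- floor(segment_s / spec$frame_step)   # frames per segment
  if (n_t < 2) stop("segment_s too short for the frame step", call. = FALSE)
  n_frames <- nrow(spec$values)
  n_seg <- n_frames %/% n_t
  if (n_seg < 1) {
    stop("recording shorter than one analysis segment (",
         sprintf("%.2f", segment_s), " s needed)", call. = FALSE)
  }
  n_f <- ncol(spec$values)

  tm_all <- fft_freqs(n_t, 1 / (n_t * spec$frame_step))        # Hz
  sm_all <- fft_freqs(n_f, 1000 / (n_f * spec$freq_step))      # cycles/kHz

  pw <- matrix(0, n_t, n_f)
  for (s in seq_len(n_seg)) {
    seg <- spec$values[((s - 1) * n_t + 1):(s * n_t), , drop = FALSE]
    seg <- seg - mean(seg)
    pw <- pw + Mod(stats::fft(seg))^2 / (n_t * n_f)
  }
  pw <- pw / n_seg
  total_uncropped <- sum(pw)

  # fold to sm >= 0: conjugate symmetry P(-t,-f) = P(t,f) means the sm >= 0
  # half with both tm signs carries all distinct pixels (the sm = 0 row is
  # internally symmetric in tm).
  tm_ord <- order(tm_all)
  sm_keep <- which(sm_all >= 0 & sm_all <= sm_max)
  sm_keep <- sm_keep[order(sm_all[sm_keep])]
  tm_keep <- tm_ord[abs(tm_all[tm_ord]) <= tm_max]

  # sign convention: negate tm so that down-sweeps (spectrogram ridges
  # falling in frequency over time) land in the positive half-plane
  power <- pw[tm_keep, sm_keep, drop = FALSE]
  tm_axis <- -tm_all[tm_keep]
  o <- order(tm_axis)
  power <- power[o, , drop = FALSE]
  tm_axis <- tm_axis[o]
  sm_axis <- sm_all[sm_keep]

  structure(list(
    power = power,
    tm_axis = tm_axis, sm_axis = sm_axis,
    tm_step = 1 / (n_t * spec$frame_step),
    sm_step = 1000 / (n_f * spec$freq_step),
    tm_max = tm_max, sm_max = sm_max,
    n_segments = n_seg,
    normalized = FALSE,
    total_power_uncropped = total_uncropped,
    grid_meta = list(segment_s = segment_s, n_t = n_t, n_f = n_f,
                     frame_step = spec$frame_step, freq_step = spec$freq_step,
                     window_bandwidth = spec$window_bandwidth,
                     floor_db = spec$floor_db)
  ), class = "modulation_spectrum")
}

# FFT bin frequencies (two-sided), step = df
fft_freqs <- function(n, df) {
  k <- seq_len(n) - 1
  k[k > n / 2] <- k[k > n / 2] - n
  k * df
}

#' Normalize a modulation spectrum to a probability distribution
#'
#' Divides power by its grand total over the cropped grid, so the SMS can
#' be read as a probability distribution of spectro-temporal modulations.
#'
#' @param mps A \code{modulation_spectrum}.
#' @return The normalized \code{modulation_spectrum} (\code{normalized = TRUE}).
#' @export
normalize_mps <- function(mps) {
  stopifnot(inherits(mps, "modulation_spectrum"))
  tot <- sum(mps$power)
  if (tot <= 0) stop("all-zero modulation spectrum", call. = FALSE)
  mps$power <- mps$power / tot
  mps$normalized <- TRUE
  mps
}

#' Energy fraction in a temporal-modulation band
#'
#' Sums normalized power over pixels with \code{lo < |tm| <= hi} (both
#' half-planes, all spectral modulations). Named bands follow the standard
#' articulatory reading of the speech modulation spectrum: syllabic rhythm
#' 2-10 Hz, formant transitions 10-40 Hz, place of articulation 40-100 Hz.
#' Bands are half-open on the left so that adjacent named bands partition
#' the axis exactly.
#'
#' @param mps A normalized \code{modulation_spectrum}.
#' @param band \code{"syllabic"}, \code{"formant_transition"},
#'   \code{"place"}, or a numeric \code{c(lo, hi)} in Hz.
#' @return The energy fraction (scalar in [0, 1]).
#' @export
band_energy <- function(mps, band = c("syllabic", "formant_transition", "place")) {
  stopifnot(inherits(mps, "modulation_spectrum"))
  if (!mps$normalized) stop("band_energy requires a normalized MPS", call. = FALSE)
  if (is.character(band)) {
    band <- match.arg(band)
    band <- switch(band, syllabic = c(2, 10),
                   formant_transition = c(10, 40), place = c(40, 100))
  }
  if (length(band) != 2 || band[1] < 0 || band[2] <= band[1]) {
    stop("band must be c(lo, hi) with 0 <= lo < hi", call. = FALSE)
  }
  if (band[2] > mps$tm_max) {
    stop("band exceeds the temporal-modulation grid (tm_max = ",
         mps$tm_max, " Hz)", call. = FALSE)
  }
  at <- abs(mps$tm_axis)
  rows <- at > band[1] & at <= band[2]
  sum(mps$power[rows, , drop = FALSE])
}

#' @export
print.modulation_spectrum <- function(x, ...) {
  cat(sprintf(
    "<modulation_spectrum> %d x %d pixels; tm %.4g Hz/px in [%.4g, %.4g], sm %.4g cyc/kHz/px; %d segment(s)%s\n",
    nrow(x$power), ncol(x$power), x$tm_step, min(x$tm_axis), max(x$tm_axis),
    x$sm_step, x$n_segments, if (x$normalized) "; normalized" else ""))
  invisible(x)
}
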