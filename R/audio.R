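#' Construct an audio signal
#'
#' The basic container of the DSP stages: a mono waveform plus its sample
#' rate. Amplitudes are expected in [-1, 1].
#'
#' @param samples Numeric vector of amplitudes.
#' @param rate Sample rate in Hz (> 0).
#' @return An object of class \code{audio_signal}.
#' @export
audio_signal <- function(samples, rate) {
  stopifnot(is.numeric(samples), is.null(dim(samples)))
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("rate must be a single positive number", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.3f s), peak %.4f\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              if (length(x$samples)) max(abs(x$samples)) else NA_real_))
  invisible(x)
}

#' Preprocessing configuration
#'
#' @param target_rate Target sample rate in Hz. Default 22050.
#' @param target_db Normalization target in dB re full scale (negative).
#'   Default -18.
#' @param normalization_mode \code{"peak"} (default) or \code{"rms"}: whether
#'   \code{target_db} refers to the peak amplitude or the RMS level.
#' @param trim_enabled Remove long sub-threshold (non-speech) stretches?
#'   Default \code{FALSE}, so pre-cleaned recordings pass through untouched.
#' @param trim_threshold_db Frames this many dB below the active level count
#'   as silence (negative). Default -40.
#' @param trim_min_gap_s Only silent runs longer than this many seconds are
#'   removed. Default 0.25.
#' @return A list of class \code{preprocess_config}.
#' @export
preprocess_config <- function(target_rate = 22050,
                              target_db = -18,
                              normalization_mode = c("peak", "rms"),
                              trim_enabled = FALSE,
                              trim_threshold_db = -40,
                              trim_min_gap_s = 0.25) {
  normalization_mode <- match.arg(normalization_mode)
  if (target_rate <= 0) stop("target_rate must be > 0", call. = FALSE)
  if (target_db >= 0) stop("target_db must be < 0 (dB re full scale)", call. = FALSE)
  if (trim_threshold_db >= 0) stop("trim_threshold_db must be < 0", call. = FALSE)
  structure(list(target_rate = target_rate, target_db = target_db,
                 normalization_mode = normalization_mode,
                 trim_enabled = trim_enabled,
                 trim_threshold_db = trim_threshold_db,
                 trim_min_gap_s = trim_min_gap_s),
            class = "preprocess_config")
}

#' Band-limited resampling (Kaiser-windowed sinc interpolation)
#'
#' Polyphase windowed-sinc resampler. For a rational rate ratio the
#' interpolation phases repeat, so tap weights are computed once per phase.
#' Passband gain error is well below 0.1 dB for band-limited input.
#'
#' @param sig An \code{audio_signal}.
#' @param target_rate Desired rate in Hz.
#' @param zeros Half-width of the sinc kernel in zero crossings at the
#'   cutoff. Default 13.
#' @param beta Kaiser window shape parameter. Default 8.
#' @return An \code{audio_signal} at \code{target_rate}.
#' @export
resample_audio <- function(sig, target_rate, zeros = 13, beta = 8) {
  stopifnot(inherits(sig, "audio_signal"))
  fs_in <- sig$rate
  if (fs_in == target_rate) return(sig)
  x <- sig$samples
  n_in <- length(x)

  g <- function(a, b) if (b == 0) a else Recall(b, a %% b)
  d <- g(round(target_rate), round(fs_in))
  p <- round(target_rate) / d              # upsampling factor
  q <- round(fs_in) / d                    # downsampling factor

  ratio <- target_rate / fs_in
  fc <- min(1, ratio)                      # cutoff in input-Nyquist units
  K <- ceiling(zeros / fc)                 # kernel half-width, input samples
  n_out <- floor(n_in * ratio)

  j <- seq_len(n_out) - 1                  # 0-based output index
  i0 <- (j * q) %/% p                      # integer part of input position
  phase <- (j * q) %% p                    # p distinct fractional phases
  fracs <- unique(phase) / p
  phase_id <- match(phase / p, fracs)

  # tap weights per phase: Kaiser-windowed sinc at offsets k - frac
  k_off <- (-K):K
  u <- outer(k_off, fracs, function(k, f) k - f)
  s <- ifelse(u == 0, fc, sin(pi * fc * u) / (pi * u))
  w <- besselI(beta * sqrt(pmax(0, 1 - (u / K)^2)), 0) / besselI(beta, 0)
  W <- s * w                                # (2K+1) x n_phases

  xp <- c(rep(0, K), x, rep(0, K + 1))
  y <- numeric(n_out)
  for (ki in seq_along(k_off)) {
    y <- y + xp[i0 + k_off[ki] + K + 1] * W[ki, phase_id]
  }
  audio_signal(pmax(-1, pmin(1, y)), target_rate)
}

#' Load and standardize a WAV recording
#'
#' Reads a PCM WAV file, averages channels to mono, and resamples to the
#' configured target rate (default 22,050 Hz). Amplitudes are scaled to
#' [-1, 1].
#'
#' @param path Path to a readable WAV file.
#' @param config A \code{\link{preprocess_config}}.
#' @return An \code{audio_signal} at \code{config$target_rate}.
#' @export
load_audio <- function(path, config = preprocess_config()) {
  w <- read_wav(path)
  if (nrow(w$samples) == 0) {
    stop("zero-length audio: ", path, call. = FALSE)
  }
  mono <- rowMeans(w$samples)              # channel mean, not channel 1
  resample_audio(audio_signal(mono, w$rate), config$target_rate)
}

#' Normalize signal amplitude to a target dB level
#'
#' Applies a pure gain so that the peak (mode \code{"peak"}) or RMS
#' (mode \code{"rms"}) amplitude equals \code{10^(target_db/20)}.
#'
#' @param sig An \code{audio_signal} with at least one nonzero sample.
#' @param target_db Target level in dB re full scale (e.g. -18).
#' @param mode \code{"peak"} or \code{"rms"}.
#' @return The gain-scaled \code{audio_signal}.
#' @export
normalize_amplitude <- function(sig, target_db = -18,
                                mode = c("peak", "rms")) {
  stopifnot(inherits(sig, "audio_signal"))
  mode <- match.arg(mode)
  level <- switch(mode,
                  peak = max(abs(sig$samples)),
                  rms  = sqrt(mean(sig$samples^2)))
  if (!is.finite(level) || level == 0) {
    stop("cannot normalize silence (all-zero signal)", call. = FALSE)
  }
  gain <- 10^(target_db / 20) / level
  audio_signal(sig$samples * gain, sig$rate)
}

#' Remove long sub-threshold (non-speech) stretches
#'
#' An automatic energy gate: the signal is cut into short frames (10 ms),
#' each frame's RMS level in dB is compared against the active level (the
#' loudest frame) plus \code{trim_threshold_db}, and runs of sub-threshold
#' frames longer than \code{trim_min_gap_s} are removed. Retained frames
#' keep their sample values exactly.
#'
#' @param sig A standardized \code{audio_signal}.
#' @param config A \code{\link{preprocess_config}} supplying
#'   \code{trim_threshold_db} and \code{trim_min_gap_s}.
#' @return The trimmed \code{audio_signal}.
#' @export
trim_nonspeech <- function(sig, config = preprocess_config()) {
  stopifnot(inherits(sig, "audio_signal"))
  frame_len <- max(1L, round(0.010 * sig$rate))
  n <- length(sig$samples)
  n_frames <- ceiling(n / frame_len)
  idx <- rep(seq_len(n_frames), each = frame_len, length.out = n)
  rms2 <- tapply(sig$samples^2, idx, mean)
  frame_db <- 10 * log10(pmax(rms2, .Machine$double.xmin))

  active_db <- max(frame_db)
  if (!is.finite(active_db) || max(rms2) == 0) {
    stop("entirely silent signal: nothing above the trim threshold",
         call. = FALSE)
  }
  silent <- frame_db < (active_db + config$trim_threshold_db)

  min_gap_frames <- ceiling(config$trim_min_gap_s / (frame_len / sig$rate))
  r <- rle(as.vector(silent))
  drop_run <- r$values & (r$lengths > min_gap_frames)
  keep_frame <- rep(!drop_run, r$lengths)
  if (!any(keep_frame)) {
    stop("entirely sub-threshold signal after trimming", call. = FALSE)
  }
  keep <- keep_frame[idx]
  audio_signal(sig$samples[keep], sig$rate)
}

#' Duration of a (cleaned) recording, in seconds
#'
#' The articulation time: length of the signal divided by its rate. Used
#' downstream as the "duration" covariate of the hierarchical model.
#'
#' @param sig An \code{audio_signal}.
#' @return Duration in seconds.
#' @export
articulation_time <- function(sig) {
  stopifnot(inherits(sig, "audio_signal"))
  length(sig$samples) / sig$rate
}

#' Full preprocessing chain
#'
#' load (if given a path) -> mono/resample -> optional silence trim ->
#' amplitude normalization. The normalization runs last so the output level
#' is exact regardless of trimming.
#'
#' @param x An \code{audio_signal} or a WAV path.
#' @param config A \code{\link{preprocess_config}}.
#' @return A standardized, normalized \code{audio_signal}.
#' @export
preprocess_audio <- function(x, config = preprocess_config()) {
  sig <- if (inherits(x, "audio_signal")) {
    resample_audio(x, config$target_rate)
  } else {
    load_audio(x, config)
  }
  if (config$trim_enabled) sig <- trim_nonspeech(sig, config)
  normalize_amplitude(sig, config$target_db, config$normalization_mode)
}
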