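#' Generate synthetic audio with known modulation content
#'
#' Three test-signal families, each deterministic given \code{seed}:
#' \describe{
#'   \item{tone}{a pure sinusoid -- no temporal modulation, so virtually
#'     all modulation power sits in the 0 Hz column.}
#'   \item{am_noise}{white noise with a raised-cosine envelope
#'     \eqn{(1 + cos(2\pi f_{am} t))/2} -- a single known temporal
#'     modulation rate.}
#'   \item{speech_like}{a bundle of formant-like carriers with
#'     syllabic-rate envelopes and slow frequency drifts. \code{richness}
#'     in [0, 1] scales the number and spread of envelope rates and the
#'     drift depth, so modulation diversity -- and hence articulation
#'     space -- grows with it. It is a modulation-bundle synthesizer, not
#'     speech synthesis: controllable modulation content, not
#'     intelligibility.}
#' }
#'
#' @param kind \code{"am_noise"}, \code{"tone"} or \code{"speech_like"}.
#' @param duration_s Duration in seconds (use >= 2 s for MPS fixtures).
#' @param rate Sample rate in Hz. Default 22050.
#' @param am_rate_hz AM rate for \code{am_noise}, Hz. Default 8.
#' @param tone_hz Frequency for \code{tone}, Hz. Default 1000.
#' @param richness Modulation diversity for \code{speech_like}, in [0, 1].
#' @param seed Integer seed; fixes the waveform bit-exactly.
#' @return An \code{audio_signal} with peak amplitude 0.95.
#' @export
generate_audio <- function(kind = c("am_noise", "tone", "speech_like"),
                           duration_s = 4, rate = 22050,
                           am_rate_hz = 8, tone_hz = 1000,
                           richness = 0.5, seed = 1) {
  kind <- match.arg(kind)
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  n <- round(duration_s * rate)
  t <- (seq_len(n) - 1) / rate

  x <- with_seed(seed, switch(
    kind,
    tone = sin(2 * pi * tone_hz * t),
    am_noise = stats::rnorm(n) * (1 + cos(2 * pi * am_rate_hz * t)) / 2,
    speech_like = speech_like_waveform(t, rate, richness)
  ))

  peak <- max(abs(x))
  if (peak == 0) stop("degenerate zero waveform", call. = FALSE)
  audio_signal(0.95 * x / peak, rate)
}

# Formant-bundle synthesizer. Carriers near canonical formant frequencies,
# each frequency-drifting and amplitude-modulated by a mixture of
# envelope rates; richness widens the rate spread (towards the 10-100 Hz
# segmental range) and deepens the drift.
speech_like_waveform <- function(t, rate, richness) {
  if (richness < 0 || richness > 1) {
    stop("richness must lie in [0, 1]", call. = FALSE)
  }
  formants <- c(500, 1500, 2500)
  n <- length(t)
  n_rates <- 1L + round(7 * richness)         # envelope components per band
  x <- numeric(n)
  for (f0 in formants) {
    # syllabic base rate plus, with richness, faster segmental rates
    rates <- c(stats::runif(1, 2, 10),
               if (n_rates > 1)
                 exp(stats::runif(n_rates - 1, log(2), log(10 + 90 * richness))))
    phases <- stats::runif(length(rates), 0, 2 * pi)
    env <- rep(1, n)
    for (j in seq_along(rates)) {
      env <- env * (1 + cos(2 * pi * rates[j] * t + phases[j])) / 2
    }
    # slow smooth frequency drift: random-walk nodes at ~4 Hz, cosine-
    # interpolated; depth grows with richness
    node_step <- max(2L, round(rate / 4))
    n_nodes <- ceiling(n / node_step) + 1L
    depth <- 0.02 + 0.25 * richness
    nodes <- stats::runif(n_nodes, -1, 1) * depth
    pos <- (seq_len(n) - 1) / node_step
    i0 <- floor(pos); frac <- pos - i0
    cfrac <- (1 - cos(pi * frac)) / 2
    drift <- nodes[i0 + 1] * (1 - cfrac) + nodes[i0 + 2] * cfrac
    freq <- f0 * (1 + drift)
    phase <- 2 * pi * cumsum(freq) / rate
    x <- x + env * sin(phase + stats::runif(1, 0, 2 * pi))
  }
  x
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with \code{set.seed(seed)} and restores the caller's
#' RNG state afterwards, so generators are deterministic without
#' perturbing the session's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
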