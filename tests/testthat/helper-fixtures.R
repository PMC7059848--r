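# Shared fixtures and independent oracles.

# Toy modulation spectrum on an explicit grid, for contour tests that need
# hand-checkable numbers. power: matrix (tm x sm); tm_axis: Hz.
toy_mps <- function(power, tm_axis, sm_axis = seq_len(ncol(power)),
                    normalized = FALSE) {
  structure(list(
    power = power, tm_axis = tm_axis, sm_axis = sm_axis,
    tm_step = if (length(tm_axis) > 1) diff(tm_axis)[1] else 1,
    sm_step = 1, tm_max = max(100, max(abs(tm_axis))), sm_max = max(sm_axis),
    n_segments = 1L, normalized = normalized,
    total_power_uncropped = sum(power),
    grid_meta = list()
  ), class = "modulation_spectrum")
}

# Brute-force contour oracle: try every distinct pixel power as the level,
# keep the highest level whose mask reaches the energy fraction.
brute_force_contour <- function(power, fraction) {
  total <- sum(power)
  levels <- sort(unique(as.vector(power)), decreasing = TRUE)
  for (lv in levels) {
    if (sum(power[power >= lv]) >= fraction * total - 1e-12 * total) {
      return(list(level = lv, area_px = sum(power >= lv),
                  fraction_achieved = sum(power[power >= lv]) / total))
    }
  }
  list(level = min(levels), area_px = length(power), fraction_achieved = 1)
}

# FFT-based analytic envelope (independent of package code): Hilbert
# transform via spectrum one-siding.
analytic_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else h[2:((n + 1) / 2)] <- 2
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Dominant nonzero frequency of a signal, Hz (oracle for AM rates).
dominant_freq <- function(x, rate) {
  x <- x - mean(x)
  sp <- Mod(stats::fft(x))[seq_len(floor(length(x) / 2))]
  freqs <- (seq_along(sp) - 1) * rate / length(x)
  keep <- freqs > 0.5
  freqs[keep][which.max(sp[keep])]
}

# Write a sine fixture WAV and return its path.
write_tone_wav <- function(freq = 440, duration_s = 1, rate = 22050,
                           amp = 0.5, channels = 1) {
  t <- (seq_len(round(duration_s * rate)) - 1) / rate
  x <- amp * sin(2 * pi * freq * t)
  if (channels == 2) x <- cbind(x, x)
  path <- tempfile(fileext = ".wav")
  artispace:::write_wav(x, rate, path)
  path
}

# Small manifest + features pair for join tests.
tiny_records <- function(n_pairs = 4, seed = 1) {
  generate_cohort(
    design = data.frame(country = c("India", "Italy"),
                        gender = c("male", "female"),
                        n_pairs = c(ceiling(n_pairs / 2), floor(n_pairs / 2))),
    seed = seed)$records
}
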