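test_that("a pure tone concentrates every spectrogram frame at its frequency bin", {
  sig <- generate_audio("tone", duration_s = 1, tone_hz = 1000, seed = 1)
  sp <- compute_spectrogram(sig)
  peaks <- apply(sp$values, 1, which.max)
  target <- which.min(abs(sp$freqs - 1000))
  expect_true(all(abs(peaks - target) <= 1))
})

test_that("a two-tone mixture shows exactly two ridges in every frame", {
  rate <- 22050
  t <- (seq_len(rate) - 1) / rate
  sig <- audio_signal(0.4 * sin(2 * pi * 500 * t) + 0.4 * sin(2 * pi * 2000 * t),
                      rate)
  sp <- compute_spectrogram(sig)
  b1 <- which.min(abs(sp$freqs - 500))
  b2 <- which.min(abs(sp$freqs - 2000))
  frame_max <- apply(sp$values, 1, max)
  # both ridge bins sit within 3 dB of the frame maximum, every frame
  expect_true(all(sp$values[, b1] > frame_max - 3))
  expect_true(all(sp$values[, b2] > frame_max - 3))
  # and nothing away from the ridges comes close (the Gaussian window's
  # skirt spans a few bins, so exclude +/- 10 bins around each ridge)
  others <- setdiff(seq_along(sp$freqs),
                    c(b1 + (-10:10), b2 + (-10:10)))
  expect_true(all(apply(sp$values[, others], 1, max) < frame_max - 20))
})

test_that("signals shorter than a window or a segment raise degenerate-input errors", {
  short <- audio_signal(stats::rnorm(100), 22050)
  expect_error(compute_spectrogram(short), "shorter than one analysis window")
  half <- generate_audio("am_noise", duration_s = 0.5, seed = 1)
  expect_error(compute_mps(compute_spectrogram(half)),
               "shorter than one analysis segment")
})

test_that("AM-noise temporal-modulation peak matches the envelope-FFT oracle", {
  for (rate_hz in c(4, 8, 16, 32)) {
    sig <- generate_audio("am_noise", duration_s = 3, am_rate_hz = rate_hz,
                          seed = 100 + rate_hz)
    # independent oracle: dominant frequency of the analytic envelope
    env <- analytic_envelope(sig$samples)
    oracle_hz <- dominant_freq(env, sig$rate)
    expect_lt(abs(oracle_hz - rate_hz), 0.5)

    mps <- normalize_mps(compute_mps(compute_spectrogram(sig)))
    marg <- rowSums(mps$power)
    off <- abs(mps$tm_axis) > 0.5
    peak_tm <- abs(mps$tm_axis[off][which.max(marg[off])])
    expect_lt(abs(peak_tm - rate_hz), mps$tm_step + 1e-9)
  }
})

test_that("a stationary tone puts >= 99% of MPS power in the zero-modulation column", {
  sig <- generate_audio("tone", duration_s = 3, seed = 5)
  mps <- normalize_mps(compute_mps(compute_spectrogram(sig)))
  dc <- which.min(abs(mps$tm_axis))
  expect_gte(sum(mps$power[dc, ]), 0.99)
})

test_that("uncropped MPS power satisfies Parseval against the spectrogram variance", {
  sig <- generate_audio("am_noise", duration_s = 3, am_rate_hz = 8, seed = 42)
  sp <- compute_spectrogram(sig)
  mps <- compute_mps(sp)
  n_t <- mps$grid_meta$n_t
  ss <- vapply(seq_len(mps$n_segments), function(s) {
    seg <- sp$values[((s - 1) * n_t + 1):(s * n_t), ]
    sum((seg - mean(seg))^2)
  }, numeric(1))
  expect_equal(mps$total_power_uncropped, mean(ss), tolerance = 1e-6)
})

test_that("normalization yields a unit-sum distribution invariant to power scaling", {
  sig <- generate_audio("am_noise", duration_s = 2, seed = 9)
  mps <- compute_mps(compute_spectrogram(sig))
  nm <- normalize_mps(mps)
  expect_equal(sum(nm$power), 1, tolerance = 1e-9)
  scaled <- mps
  scaled$power <- scaled$power * 7
  expect_equal(normalize_mps(scaled)$power, nm$power, tolerance = 1e-12)
})

test_that("waveform gain and polarity leave the normalized MPS unchanged", {
  sig <- generate_audio("speech_like", duration_s = 2, richness = 0.5, seed = 3)
  chain <- function(s) normalize_mps(compute_mps(compute_spectrogram(s)))$power
  ref <- chain(sig)
  expect_equal(chain(audio_signal(sig$samples * 0.5, sig$rate)), ref,
               tolerance = 1e-9)
  expect_equal(chain(audio_signal(-sig$samples, sig$rate)), ref,
               tolerance = 1e-12)
})

test_that("temporal-modulation bands partition and order as constructed", {
  sig <- generate_audio("am_noise", duration_s = 3, am_rate_hz = 8, seed = 42)
  mps <- normalize_mps(compute_mps(compute_spectrogram(sig)))
  parts <- c(band_energy(mps, c(1, 2)), band_energy(mps, "syllabic"),
             band_energy(mps, "formant_transition"), band_energy(mps, "place"))
  expect_equal(sum(parts), band_energy(mps, c(1, 100)), tolerance = 1e-9)
  # 8 Hz AM concentrates energy in the syllabic band
  expect_gt(parts[2], parts[3])
  expect_gt(parts[2], parts[4])
  expect_error(band_energy(mps, c(150, 200)), "exceeds")
})

test_that("the MPS grid shape depends on parameters, not recording duration", {
  a <- compute_mps(compute_spectrogram(generate_audio("am_noise", 2.2, seed = 1)))
  b <- compute_mps(compute_spectrogram(generate_audio("am_noise", 5.4, seed = 2)))
  expect_identical(dim(a$power), dim(b$power))
  expect_identical(a$tm_axis, b$tm_axis)
  expect_identical(a$sm_axis, b$sm_axis)
})

test_that("averaging more segments stabilizes the normalized MPS", {
  cv <- function(dur, n_seg_label, seeds = 1:4) {
    stack <- sapply(seeds, function(s) {
      sig <- generate_audio("am_noise", duration_s = dur, am_rate_hz = 8,
                            seed = 2000 + s)
      as.vector(normalize_mps(compute_mps(compute_spectrogram(sig)))$power)
    })
    mu <- rowMeans(stack)
    keep <- mu > stats::quantile(mu, 0.9)   # pixels carrying real energy
    mean(apply(stack[keep, ], 1, stats::sd) / mu[keep])
  }
  expect_lt(cv(8.05), cv(2.05))
})
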