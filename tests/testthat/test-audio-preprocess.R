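test_that("WAV write-then-load round trip is exact to 16-bit quantization", {
  rate <- 22050
  t <- (seq_len(rate) - 1) / rate
  x <- 0.5 * sin(2 * pi * 440 * t)
  path <- tempfile(fileext = ".wav")
  artispace:::write_wav(x, rate, path)
  sig <- load_audio(path)
  expect_equal(sig$rate, 22050)
  expect_lte(max(abs(sig$samples - x)), 2^-15 + 1e-12)
})

test_that("stereo 44.1 kHz input becomes mono 22.05 kHz of half the length", {
  n <- 44100 * 2
  t <- (seq_len(n) - 1) / 44100
  left <- 0.4 * sin(2 * pi * 500 * t)
  path <- tempfile(fileext = ".wav")
  artispace:::write_wav(cbind(left, left), 44100, path)
  sig <- load_audio(path)
  expect_equal(sig$rate, 22050)
  expect_lte(abs(length(sig$samples) - round(n * 22050 / 44100)), 1)
})

test_that("resampled ramp matches an independent linear-interpolation oracle", {
  n <- 4000
  ramp <- seq(0, 1, length.out = n) * 0.8
  out <- resample_audio(audio_signal(ramp, 44100), 22050)
  expect_lte(abs(length(out$samples) - n / 2), 1)
  # away from the edges a band-limited resampler tracks a straight line
  mid <- 200:(length(out$samples) - 200)
  oracle <- approx(seq_len(n), ramp, xout = 1 + (mid - 1) * 2)$y
  expect_lt(max(abs(out$samples[mid] - oracle)), 1e-3)
})

test_that("degenerate audio files raise I/O errors naming the path", {
  empty <- tempfile(fileext = ".wav")
  file.create(empty)
  expect_error(load_audio(empty), "wav", ignore.case = TRUE)
  expect_error(load_audio(tempfile(fileext = ".wav")), "no such file")
})

test_that("peak normalization hits the closed-form -18 dB level and is idempotent", {
  rate <- 22050
  t <- (seq_len(rate) - 1) / rate
  sig <- audio_signal(sin(2 * pi * 440 * t), rate)
  nrm <- normalize_amplitude(sig, -18, "peak")
  expect_equal(max(abs(nrm$samples)), 10^(-18 / 20), tolerance = 1e-12)
  twice <- normalize_amplitude(nrm, -18, "peak")
  expect_equal(twice$samples, nrm$samples, tolerance = 1e-12)
  # pure gain: waveform shape unchanged
  expect_equal(nrm$samples / max(abs(nrm$samples)),
               sig$samples / max(abs(sig$samples)), tolerance = 1e-12)
})

test_that("rms normalization of an RMS-0.5 sine applies gain 0.25178", {
  rate <- 22050
  t <- (seq_len(rate) - 1) / rate
  x <- sqrt(2) * 0.5 * sin(2 * pi * 441 * t)   # RMS exactly 0.5 (whole periods)
  expect_equal(sqrt(mean(x^2)), 0.5, tolerance = 1e-6)
  nrm <- normalize_amplitude(audio_signal(x, rate), -18, "rms")
  expect_equal(sqrt(mean(nrm$samples^2)), 10^(-18 / 20), tolerance = 1e-6)
  expect_equal(nrm$samples[100] / x[100], 10^(-18 / 20) / 0.5, tolerance = 1e-6)
})

test_that("all-zero signals cannot be normalized or trimmed", {
  z <- audio_signal(rep(0, 1000), 22050)
  expect_error(normalize_amplitude(z), "silence")
  expect_error(trim_nonspeech(z), "silent")
})

test_that("silence trimming removes zero padding but keeps the tone", {
  rate <- 22050
  t <- (seq_len(rate) - 1) / rate
  tone <- 0.5 * sin(2 * pi * 440 * t)
  padded <- audio_signal(c(rep(0, rate / 2), tone, rep(0, rate / 2)), rate)
  cfg <- preprocess_config(trim_enabled = TRUE, trim_threshold_db = -40)
  trimmed <- trim_nonspeech(padded, cfg)
  expect_lt(abs(articulation_time(trimmed) - 1), 0.02)  # within ~1 frame
  # retained samples keep their values
  expect_true(all(trimmed$samples %in% padded$samples))
})

test_that("trimming is the identity when nothing is sub-threshold, and never lengthens", {
  rate <- 22050
  sig <- audio_signal(0.5 * sin(2 * pi * 300 * (seq_len(rate) - 1) / rate), rate)
  out <- trim_nonspeech(sig, preprocess_config(trim_enabled = TRUE))
  expect_identical(out$samples, sig$samples)
  padded <- audio_signal(c(rep(0, rate), sig$samples), rate)
  out2 <- trim_nonspeech(padded, preprocess_config(trim_enabled = TRUE))
  expect_lte(length(out2$samples), length(padded$samples))
})

test_that("articulation time is samples over rate", {
  expect_equal(articulation_time(audio_signal(numeric(22050), 22050)), 1.0)
  expect_equal(articulation_time(audio_signal(numeric(33075), 22050)), 1.5)
})

test_that("the preprocessing chain is idempotent and preserves duration when trim is off", {
  sig <- generate_audio("speech_like", duration_s = 1, richness = 0.5, seed = 2)
  cfg <- preprocess_config()
  once <- preprocess_audio(sig, cfg)
  twice <- preprocess_audio(once, cfg)
  expect_equal(twice$samples, once$samples, tolerance = 2^-15)
  expect_equal(length(once$samples), length(sig$samples))
})

test_that("normalization commutes with resampling to within 0.1 dB", {
  t <- (seq_len(44100) - 1) / 44100
  sig <- audio_signal(0.7 * sin(2 * pi * 1000 * t), 44100)
  a <- resample_audio(normalize_amplitude(sig, -18, "rms"), 22050)
  b <- normalize_amplitude(resample_audio(sig, 22050), -18, "rms")
  lvl <- function(s) 20 * log10(sqrt(mean(s$samples^2)))
  expect_lt(abs(lvl(a) - lvl(b)), 0.1)
})
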