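---
title: "Methods: the articulation space of speech and its dyadic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the articulation space of speech and its dyadic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artispace)
```

## The problem

Speech is organized by joint spectro-temporal events on several time
scales at once: syllabic rhythm around 2–10 Hz, formant transitions around
10–40 Hz, place-of-articulation cues around 40–100 Hz. A speaker who
modulates their voice richly — socially engaged speech, expressive
prosody — samples more of these modulations than one who speaks in a
monotone. `artispace` measures that richness as a single number per
recording and models its variation across speakers who are nested in
conversational dyads, where closeness to the partner (a 0–10 rating, CR)
and autistic traits (the Autism Spectrum Quotient, AQ) are the covariates
of interest.

## From waveform to articulation space

### Standardization

Recordings are averaged to mono (channel mean, robust to stereo input),
resampled to 22,050 Hz with a Kaiser-windowed polyphase sinc interpolator
(passband gain error < 0.01 dB on a 1 kHz tone — well inside the 0.1 dB we
consider negligible for a level-normalized pipeline), and scaled so the
peak amplitude is −18 dB re full scale. "−18 dB" does not name a
measurement convention by itself; we default to **peak** normalization
(what audio editors call "normalize") and expose RMS as
`preprocess_config(normalization_mode = "rms")`. Because the modulation
spectrum is gain-invariant by construction (below), this choice does not
affect the articulation space; it only standardizes headroom.

Silence trimming (`trim_enabled`) is **off** by default: the pipeline
expects recordings already cleaned of non-speech. When enabled, a 10 ms
energy gate removes runs of frames more than `trim_threshold_db` (default
−40 dB) below the loudest frame lasting longer than `trim_min_gap_s`
(default 0.25 s). This is an automatic approximation to manual editing and
is labelled as such; retained samples are untouched, so trimming never
alters the retained waveform.

### Spectrogram

Short-time Fourier magnitude with a Gaussian window whose *spectral*
standard deviation is 50 Hz (temporal σ = 1/(2π·50) ≈ 3.18 ms), truncated
at ±5σ so the truncation sidelobes (≈ −108 dB) fall below the analysis
floor. The hop is `round(22050 × 0.001)` = 22 samples, i.e. a realized
frame step of 0.9977 ms; the temporal-modulation Nyquist is therefore
≈ 500 Hz, five times the 100 Hz analysis bound. Magnitude is expressed in
dB relative to the grid maximum and clipped 80 dB down, which keeps every
value finite and gives the floor pixels a constant value.

These three numbers (50 Hz, 1 ms, 80 dB) are analysis *choices*, exposed
in `sms_config()` and stamped into every output: there is no universal
standard for them, and areas computed under different settings are not
comparable (the features table carries a configuration hash for exactly
this reason).

### The modulation spectrum

The dB spectrogram is cut into non-overlapping segments of 1 s (1002
frames at the realized frame step; a trailing remainder is discarded).
Each segment is mean-subtracted (its grand mean over all dB values) and
2-D Fourier transformed; power |F|²/(n_t·n_f) is averaged over segments.
With this scaling the total power over the uncropped grid equals the
per-segment sum of squared dB deviations — a Parseval identity the test
suite checks to 1e−6 relative error.

Two design points deserve emphasis:

* **Log-amplitude before the 2-D transform.** A waveform gain is an
  additive constant on the dB spectrogram, which per-segment mean
  subtraction removes exactly. This makes the normalized modulation
  spectrum — and therefore the articulation space, in pixels — *exactly*
  invariant to recording level, a property the tests assert as pixel
  equality.
* **Fixed grid.** The grid shape depends only on (segment length, frame
  step, frequency step, crop bounds), never on duration: longer
  recordings average more segments onto the same pixels. Pixel counts are
  therefore comparable across recordings analyzed alike.

Axes are temporal modulation ω_t in Hz (signed: up-sweeps negative,
down-sweeps positive, per the usual display convention; all statistics
use |ω_t|) and spectral modulation ω_f in cycles/kHz, folded to ω_f ≥ 0 by
the point symmetry of the transform of a real grid. Defaults crop to
|ω_t| ≤ 100 Hz (the hard analysis bound) and ω_f ≤ 10 cycles/kHz (the
spectral axis needs *some* bound; 10 cycles/kHz sits below the 11.6
cycles/kHz Nyquist of the frequency sampling and beyond where speech
carries appreciable ripple density, and it is configurable).

The realized temporal-modulation step is 1/(1002 × 22/22050) ≈ 1.0003 Hz
rather than exactly 1 Hz, because hops are integer sample counts. Axis
metadata carries exact values; nothing downstream assumes whole-hertz
pixels.

### The contour and its area

On the normalized spectrum restricted to 1 ≤ |ω_t| ≤ 100 Hz, pixels are
sorted by power and included greedily until the running sum reaches the
energy fraction (default 0.99); the power of the last pixel is the contour
level, and ties at the level are all included. The pixel count is the
articulation space. This *descending-pixel* definition equals exhaustive
search over all thresholds (tested by brute force on small grids) and does
not depend on any plotting library's contour polygons.

Decisions a user can revisit:

* **Energy fraction.** 0.99 by default; 0.999 is one parameter away
  (`sms_config(fraction = 0.999)`). Published descriptions of this
  statistic differ on the digit, so both are first-class and the value is
  echoed in the features table.
* **Denominator.** The fraction is taken of the energy *within* the
  1–100 Hz band (the band is part of the statistic's definition); taking
  it of the whole-grid energy is `denominator = "grid"`.
* **Half-planes.** Both ω_t half-planes are counted (up- and down-sweeps);
  `half_planes = "positive"` counts one.

Areas are reported in pixels of this canonical grid only. They are not
convertible to Hz × cycles/kHz without the grid metadata, and they are
not comparable to areas computed on other grids.

## The dyadic model

Each speaker contributes one articulation-space value; speakers come in
same-sex pairs who rated closeness to each other. The model is

```
area ~ gender + country + age + duration + cr + aq + (1 | pair)
```

fitted by REML (`lmerTest`), with Satterthwaite approximate degrees of
freedom — dyadic data with 2 observations per cluster sit exactly where
naive df are most misleading. The default contrast scheme is **simple
coding**: gender ±0.5 (the coefficient reads male − female), country
simple-coded against Italy (coefficients read India − Italy and
UK − Italy), covariates grand-mean-centered, so the intercept estimates
the unweighted grand mean. Treatment coding is available
(`coding = "treatment"`) and the scheme used is recorded in `fit_meta` —
fixed-effect values are only interpretable jointly with their coding.
Rows missing any model variable (AQ is the realistic case) are dropped
listwise at fit time and the count is reported, not silently absorbed.

`duration` — the articulation time, in seconds of (cleaned) audio — enters
as a covariate because longer recordings average more segments and could
otherwise masquerade as modulation richness.

## What the synthetic generators emulate

`generate_audio()` produces three families with *known* modulation
content: pure tones (no temporal modulation: ≥ 99% of power lands in the
ω_t = 0 column), amplitude-modulated white noise (one programmed envelope
rate, recoverable both by the package and by an independent
envelope-FFT oracle), and `speech_like` modulation bundles — three
formant-like carriers (500/1500/2500 Hz) with syllabic-rate envelopes and
slow frequency drift whose diversity scales with a `richness` knob in
[0, 1]. Richness widens the envelope-rate spread from purely syllabic
(2–10 Hz) toward the segmental range (up to 100 Hz) and deepens the
drift, so articulation space rises monotonically with it (tested on
medians over seeds). These signals validate the *measurement chain*; they
are not speech: no phonotactics, no pauses, no pitch contour, no room
acoustics. Passing tests on them shows the DSP does what it claims, not
that any particular human population behaves any particular way.

`generate_cohort()` is the generative twin of the model: the study-sized
design (85 pairs: India 9M + 13F, Italy 10M + 10F, UK 18M + 25F), a linear
predictor on exactly the fit's coding, a shared N(0, sd_pair²) intercept
per pair and N(0, sd_resid²) residuals. Covariates are drawn uniformly on
the ranges a young-adult cohort shows (CR integer 0–10, AQ integer 5–40,
age 18–33, duration 120–180 s for a ~2.5 min speaking turn), independent
by default with an optional CR–AQ correlation knob. Defaults for the
variance components (sd_pair 30, sd_resid 50 px) give an intraclass
correlation of 0.26, a moderate dyadic dependence; they are study
conditions, set once, and the recovery simulations (bias of the closeness
slope, 95% CI coverage, type-I error at the null) are run at exactly these
conditions. Real cohorts differ in ways the generator does not model:
covariates correlate with country, AQ distributions are skewed, and the
area–covariate relation need not be linear.

## Numerical choices and degenerate inputs

* Resampler: windowed sinc, 13 zero-crossings half-width at the cutoff,
  Kaiser β = 8; phases are precomputed per rational rate ratio.
* All-zero audio, sub-window signals, sub-segment recordings, all-silent
  trims, all-zero spectra: each raises a specific degenerate-input error
  rather than propagating NaNs.
* Contour ties are included wholesale (the level is a closed threshold);
  fraction 1.0 returns every nonzero pixel of the band.
* The pipeline skips unreadable audio files with a logged reason and drops
  the orphaned partner from the model stage (a pair needs both members);
  it fails only if *all* rows fail or the manifest is empty.
* Determinism: every random draw flows from an explicit seed through
  `with_seed()`, which restores the caller's RNG state; rerunning the
  pipeline on the same inputs reproduces the features CSV byte for byte.

## Problem sizes in the shipped scripts

The analysis drivers synthesize a 12-pair study (24 recordings of ~4 s)
for the audio chain — small enough to run everywhere, large enough for a
non-degenerate model — and validate the statistical stage at the full
85-pair design over 200 recovery and 500 null replicates, where no audio
synthesis is needed. Monte-Carlo summaries at these sizes carry sampling
error of a few percent, which the acceptance bands account for.

## Known limitations

* The articulation space is grid-dependent by definition; cross-study
  comparisons require identical analysis configurations, which the config
  hash enforces only within this package's outputs.
* The energy gate is a crude stand-in for careful manual cleaning; on
  recordings with breaths, laughter or background speech it will pass
  non-speech energy into the statistic.
* The model assumes Gaussian residuals and a single random intercept;
  random slopes, gender × country interactions and non-linear covariate
  effects are out of scope.
* `speech_like` audio validates measurement, not ecology: effect sizes
  estimated from synthetic cohorts say nothing about real dyads.
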