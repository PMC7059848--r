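# artispace

Vocal modulation — how much a speaker varies intensity and frequency over
time — carries social information: people speak differently to someone they
feel close to, and reduced prosodic modulation has long been associated
with autistic traits. `artispace` implements an end-to-end analysis of this
phenomenon for dyadic speech studies: it quantifies each speaker's vocal
modulation as the **articulation space** of their recording and relates it
to interpersonal closeness and autistic traits with a hierarchical linear
model over speakers nested in pairs.

The package is aimed at researchers analyzing same-sex dyad recordings
(one monologue per speaker, pre-cleaned WAV files plus a participant
manifest), and at anyone who needs a tested, self-contained implementation
of the speech modulation spectrum and its contour-area statistic.

## The statistic

1. **Standardization.** Each recording is converted to mono, resampled to
   22,050 Hz, and amplitude-normalized to −18 dB (peak by default; RMS
   available).
2. **Spectrogram.** Short-time Fourier magnitude with a Gaussian window of
   spectral bandwidth 50 Hz, 1 ms hop, expressed in dB with an 80 dB floor.
3. **Speech modulation spectrum (SMS).** The spectrogram is cut into 1 s
   segments; each segment is mean-subtracted and 2-D Fourier transformed.
   Averaged power becomes a joint distribution over temporal modulation
   ω_t (Hz) and spectral modulation ω_f (cycles/kHz), normalized to sum
   to 1. Reading the temporal axis: 2–10 Hz ≈ syllabic rhythm, 10–40 Hz ≈
   formant transitions, 40–100 Hz ≈ place-of-articulation cues.
4. **Articulation space.** Pixels of the normalized SMS with
   1 ≤ |ω_t| ≤ 100 Hz are sorted by power and included greedily until they
   cover 99% of the band's energy. The pixel count of that contour is the
   articulation space: a speaker sampling more spectro-temporal modulations
   occupies more pixels.
5. **Model.** `area ~ gender + country + age + duration + CR + AQ +
   (1 | pair)`, fitted by REML with Satterthwaite degrees of freedom
   (CR = closeness rating 0–10, AQ = Autism Spectrum Quotient). Simple
   contrast coding: the gender effect reads male − female ("2-1"), country
   effects read against Italy, covariates are grand-mean-centered, so the
   intercept sits at the grand mean.

Synthetic generators close the loop: `generate_audio()` makes tones,
AM noise and speech-like modulation bundles with known modulation content;
`generate_cohort()` makes dyadic cohorts with known fixed effects, pair
variance and residual variance, so recovery of every stage can be tested
without any external data.

## Worked example

```r
library(artispace)

# Two synthetic 3 s signals differing only in modulation diversity
rich <- generate_audio("speech_like", duration_s = 3, richness = 0.8, seed = 1)
flat <- generate_audio("speech_like", duration_s = 3, richness = 0.1, seed = 1)
articulation_space_area(rich)$area_px   # 5117
articulation_space_area(flat)$area_px   # 4010
```

The richer signal occupies ~1,100 more pixels: more distinct
spectro-temporal modulations need more of the grid to cover 99% of the
energy.

```r
# A study-sized synthetic cohort (85 pairs / 170 speakers) and its model
coh <- generate_cohort(seed = 42)
fit_hlm(coh$records)
#> Hierarchical linear model of articulation space (REML, simple coding)
#> n = 170 participants in 85 pairs (0 dropped for missingness)
#>           term       label estimate     se   ci_lo   ci_hi      df      t     p
#>    (Intercept) (Intercept)  254.090  6.037 242.076 266.105  79.828 42.089 0.000
#>         gender         2-1   53.414 11.473  30.582  76.245  80.082  4.656 0.000
#>  country_india India-Italy  -46.100 16.290 -78.509 -13.690  81.486 -2.830 0.006
#>     country_uk    UK-Italy   20.229 14.312  -8.242  48.699  82.138  1.413 0.161
#>            age         Age    2.617  0.881   0.876   4.359 136.829  2.972 0.003
#>       duration    Duration    0.024  0.247  -0.465   0.513 142.659  0.098 0.922
#>             cr          CR    2.861  1.376   0.140   5.582 141.097  2.078 0.039
#>             aq          AQ   -1.253  0.420  -2.084  -0.423 134.908 -2.985 0.003
#> Random intercept (pair) variance: 1602.39; residual: 2249.87
```

Each row is a fixed effect with its standard error, 95% confidence
interval, Satterthwaite df, t and p. Here the cohort was generated with a
positive closeness slope and a negative AQ slope, and the fit recovers
both signs; estimates differ from the generating values only by sampling
noise, which the recovery simulation below quantifies.

## Analysis workflow

The `analysis/` scripts run the whole study on synthetic data:

```sh
Rscript analysis/01_synthesize_study.R    # 12-pair cohort + WAVs (scratch/)
Rscript analysis/02_extract_features.R    # SMS + articulation space -> results/features.csv
Rscript analysis/03_fit_model.R           # descriptives + mixed model + figures
Rscript analysis/04_recovery_simulation.R # bias/coverage/type-I at 85 pairs
```

`run_pipeline()` does steps 2–3 in one call for any manifest of WAV files.

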