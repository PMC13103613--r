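# talkerlearn

Simulation and analysis of talker-identification learning experiments
that combine choice/response-time behavior with trial-locked
pupillometry.

Listeners identify talkers far better in a language they know (the
language familiarity effect). `talkerlearn` implements the complete
analysis chain used to study how that advantage emerges during learning,
plus a generative model of the whole experiment so every stage can be
validated by parameter recovery:

* **Study simulator** — talker voice features (mean F0, F0 range, speech
  rate, jitter, harmonicity, formant dispersion), trial choices and RTs
  from a multi-alternative Wiener race with language-dependent cue
  weighting, and 1000 Hz pupil traces whose amplitude falls with the
  evidence accumulation rate (`gen_study()`, `simulate_race()`).
* **Behavior** — accuracy scoring, 3-SD log-RT screening, confusion
  matrices, and the training/test logistic and linear mixed models with
  Type III Wald tests (`fit_accuracy_model()`, `fit_rt_model()`).
* **Decision model** — the race likelihood built from the
  inverse-Gaussian first-passage law
  `f(t) = b (2 pi t^3)^(-1/2) exp(-(b - mu t)^2 / (2 t))`, exact
  sampling, quadrature win probabilities, and a Bayesian fit with
  block-varying drift `mu[d,s,block]`, threshold `b[d,s,block]` and
  per-stimulus offsets via adaptive Metropolis with a random-walk prior
  across blocks (`fit_ddm()`, `correct_params()`).
* **Pupillometry** — windowing to [-500, 4000) ms, 50 Hz block-mean
  downsampling, a strict 15% blink screen, ±120 ms linear interpolation,
  baseline percent-change normalization (`preprocess_pupil()`), and
  growth curve analysis on fourth-order orthogonal polynomials with
  participant random slopes (`fit_gca_language_block()`,
  `fit_gca_ea_rate()`).
* **Error patterns** — acoustic similarity matrices (−1 × Euclidean
  distance over the six features), Spearman correlation between
  off-diagonal confusions and similarity, and the paired language
  contrast (`asm_from_features()`, `compare_languages()`).

## Worked example

```r
library(talkerlearn)

res <- run_study_pipeline(default_config(), seed = 1)

subset(res$behavior$acc_by_block, block <= 2)
#>     language block   correct
#> 1     native     1 0.6229167
#> 2 unfamiliar     1 0.3510417
#> 3     native     2 0.6541667
#> 4 unfamiliar     2 0.3510417

co <- res$pupil$gca_language_block$coefficients
co[co$term %in% c("languageunfamiliar", "languageunfamiliar:block"), 1:3]
#>                        term    estimate         se
#> 6        languageunfamiliar  1.01673615 0.07336870
#> 16 languageunfamiliar:block -0.04974927 0.02679046

res$asm$contrast$descriptives
#>     language   mean_rho        sem
#> 1     native 0.03807591 0.03786861
#> 2 unfamiliar 0.29369198 0.03069174
```

The accuracy table shows the planted language familiarity effect
(identification is ~27 points more accurate in the native language) and
learning across blocks. The growth-curve coefficients say pupil dilation
is about 1 percentage point larger in the unfamiliar language, with the
gap narrowing by ~0.05 points per training block. The Spearman
descriptives show listeners' confusions track voice acoustics in the
unfamiliar language (rho ≈ 0.29) but barely in the native one — higher
reliance on low-level acoustic cues when higher-level cues are
unavailable.

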