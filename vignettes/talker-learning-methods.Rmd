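---
title: "Models and methods behind talkerlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind talkerlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(talkerlearn)
```

# The scientific problem

Listeners identify *who* is talking far better in a language they know —
the language familiarity effect. `talkerlearn` packages the full analysis
chain used to study how that advantage unfolds during learning: behavioral
accuracy and response-time mixed models, a multi-alternative drift
diffusion (race) model of the decision process, trial-locked pupillometry
as an index of processing cost, and an error-pattern analysis that asks
how strongly listeners' confusions track the acoustic similarity of the
voices. Because the package's correctness is established by simulation,
it also ships a first-class generative model of the whole experiment: a
study in which participants learn to identify four talkers per language
over four 40-trial training blocks plus a 40-trial test block with novel
sentences, with the pupil sampled at 1000 Hz from -500 to 4000 ms around
stimulus onset.

# The decision model

Each trial is modeled as a race among K = 4 independent Wiener evidence
accumulators, one per response option. Accumulator *d* for stimulus *s*
has drift `mu[d, s]` (evidence accumulation rate, how efficiently
decision-relevant information is extracted) and barrier `b[d, s]`
(decision threshold, response caution), with unit diffusion coefficient
for identifiability. Its first passage time is inverse-Gaussian with mean
`b/mu` and shape `b^2`, density

```
f(t; mu, b) = b (2 pi t^3)^(-1/2) exp(-(b - mu t)^2 / (2 t)).
```

The response is the first accumulator to cross, and the observed RT adds
a per-stimulus non-decision offset `delta_s` (encoding plus motor time).
The likelihood of a trial (response *d* at decision time `tau = rt -
delta_s`) is the density of accumulator *d* at `tau` times the survival
of every other accumulator at `tau` (`race_loglik()`). Probability
conservation (`sum_d integral f_d prod S_d' = 1`) and the equivalence of
three independent routes — quadrature (`race_win_prob()`), exact
inverse-Gaussian sampling (`simulate_race()`), and brute-force path
simulation (`simulate_race_paths()`) — are asserted in the test suite.

The path oracle deserves a note: plain Euler–Maruyama at a 0.1 ms step
systematically *over*-estimates first passage times, because a continuous
path can touch the barrier between grid points. At 100,000 paths this
bias exceeds Monte-Carlo error, so the oracle applies the standard
Brownian-bridge correction: after each non-crossing step from `x0` to
`x1` the path is counted as crossed with probability
`exp(-2 (b - x0)(b - x1) / dt)`.

## Bayesian fitting

`fit_ddm()` estimates `log mu[d, s, block]`, `log b[d, s, block]` and the
offsets by adaptive random-walk Metropolis (per-site proposals tuned to
a 0.44 acceptance rate during burn-in; Robbins–Monro adaptation, frozen
afterwards). Priors are lognormal(0, 1) on drifts and thresholds —
weakly informative and scale-respecting — and uniform on each offset over
(0, the minimum observed decision RT for that stimulus), sampled on the
logit scale with the appropriate Jacobian. Block-to-block change is
regularized by a Gaussian random walk on the log scale (sd `tau_rw`,
default 0.3), capturing the idea that decision parameters drift slowly
over learning; a flag switches to fully independent blocks. The default
reporting schedule is 6000 iterations, 2000 burn-in, thinning 5, and
posterior means with 95% pointwise credible intervals are reported;
block differences are declared when those intervals do not overlap
(`correct_params()` flags every block pair). The default fit pools
participants within a language; a full cross-participant hierarchy is
deliberately out of scope at this problem size.

Two properties of this model are worth knowing. First, the offset trades
off against drift and threshold along a flat likelihood ridge, so at
realistic trial counts the *marginal* posterior means of `mu` and `b`
sit a few percent below truth even though the joint maximum-likelihood
point is essentially unbiased; the sampler was cross-validated against
an independent MCMC implementation (JAGS, zeros-trick likelihood) during
development and reproduces its posterior to within Monte-Carlo error.
Second, identifiability of the off-diagonal (error) parameters is weak
when errors are rare, which is precisely why the analysis focuses on the
correct-trial (d = s) parameters.

The recovery study in the acceptance tests uses 400 trials per stimulus
per block and 20 replicates at a 2500/1000/1 schedule (the full
6000/2000/5 schedule is used for the planted block-change check); these
problem sizes keep the whole study under ten minutes while leaving the
conclusions unchanged at longer schedules, which we verified during
development.

# The study generator

`gen_study()` writes a complete synthetic study: talker feature tables,
trials, 1000 Hz pupil traces, and a ground-truth JSON sufficient to
recompute every downstream expectation.

**Talkers.** Six voice features per talker (mean F0, F0 range, speech
rate, jitter, harmonicity, formant dispersion) are drawn independently
from location/scale settings shared by both languages, so the two
languages' between-talker distance distributions are exchangeable — the
design intent of a stimulus set whose acoustic variance is comparable
across languages. The defaults (e.g. F0 170 ± 30 Hz, speech rate 4.5 ±
0.5 syll/s) are field-plausible conventions, not estimates of any real
talker set.

**Cue weighting.** The generator's central dial is the language cue
weight `w`: drifts are

```
mu[d, s] = mu_base + g(language, block) * (w * 1(d = s) + (1 - w) * sigma(d, s))
```

where `sigma` is the acoustic similarity matrix rescaled to [0, 1] with
unit diagonal. With `w = 1` errors carry no acoustic structure; with
`w = 0` error drifts are ordered exactly by similarity. Defaults plant
`w = 0.8` for the native language (identification driven by talker
identity — abstract, high-level cues) and `w = 0.2` for the unfamiliar
one (errors track voice acoustics). Because `sigma(s, s) = 1`, the
correct-choice drift is `mu_base + g` regardless of `w`, so `w` shifts
error structure and accuracy without touching the correct accumulator.

**Gain schedules.** Learning enters through the per-block gain `g`
(native `1.7, 2.0, 2.15, 2.3`; unfamiliar `0.6, 0.9, 1.13, 1.32`; the
test block reuses the final training gain). The native schedule is
uniformly higher — larger correct-choice drift margins, higher accuracy
and higher evidence accumulation rates in every block — while the
unfamiliar schedule has larger increments, so the between-language drift
gap narrows over training. The latter choice is deliberate: pupil
amplitude is tied to the correct-choice drift (below), and the empirical
signature being emulated is a pupil-dilation language gap that *shrinks*
across blocks. With a deterministic amplitude-drift link those two
patterns cannot be decoupled, so the generator favors the pupil
trajectory; the cost is that the two languages' accuracy learning rates
are nearly matched on the logit scale under defaults (the accuracy
interaction is approximately null rather than native-favored). The mixed
models' ability to recover a planted interaction is therefore tested on
an explicitly asymmetric configuration instead.

**Thresholds and response times.** Thresholds are constant over blocks
(native 1.5; unfamiliar 1.33). The unfamiliar value was calibrated once,
before any acceptance measurement, so that the two languages' expected
log response times match — mirroring the canonical empirical finding
that talker-identification RTs do not differ by language even when
accuracy does. The non-decision offset defaults to 0.35 s for every
stimulus; participants carry lognormal multipliers on gain (sd 0.12 per
participant x language) and offset (sd 0.08), which is what the random
effects in the behavioral models estimate.

**Pupil traces.** A trial's trace is
`B_p (1 + (A/100) h(t) + eps(t))`, with participant baseline `B_p`
(lognormal around 4000 a.u., 10% cv), the conventional unit-peak pupil
impulse kernel `h(t) = (t/t_max)^n exp(n (1 - t/t_max))` with n = 10.1
and t_max = 930 ms, AR(1) noise `eps` (sd 1.5%, 200 ms time constant),
and amplitude `A = max(0, a0 - a1 * mu_ss)` in percent units (a0 = 30,
a1 = 4): trials on which evidence accumulates faster dilate the pupil
less, the coupling the pupil-by-EA-rate growth curve model is built to
detect. Blinks arrive as a Poisson process (0.325 events/s, lognormal
durations around 200 ms) and mask samples as missing; the rate is a
one-time calibration yielding roughly 12% trial rejection at the 15%
screen. What the generator does *not* emulate: gaze-position artifacts,
pupil foreshortening, slow drift across a session, feedback reactivity,
or any sentence-identity effects — so passing tests validate the
pipeline's arithmetic and inferential calibration, not robustness to
every artifact of real recordings.

# Preprocessing and growth curve analysis

Preprocessing follows the fixed order window (samples in [-500, 4000)
ms) → downsample (non-overlapping 20-sample block means to 50 Hz, bin
timestamps at bin starts, a bin blink-flagged if any source sample is) →
blink screen (reject strictly above 15% flagged bins — the screen counts
bins at 50 Hz, since screening is listed after downsampling; a flag
allows screening at the source rate) → interpolation (each blink run
widened by 120 ms per side, filled linearly between nearest valid
samples, edge gaps by nearest-value extension) → baseline normalization
(percent change against the mean of [-500, 0), baseline window dropped,
output on [0, 4000) — 200 bins of 20 ms). Exact boundary conventions
(inclusive start, strict screen, retained boundary outliers) are pinned
by hand-computed fixtures in the tests.

The growth curve analysis regresses stacked per-cell mean traces on
orthonormal polynomial time terms ot1–ot4 (`stats::poly`; the
fourth-order basis matches the shape of task-evoked pupil responses, and
the package reports log-likelihoods so a third-versus-fourth-order
comparison is a one-liner). The language model has fixed effects of time
terms, language (treatment-coded, native reference), block (numeric) and
all interactions; the EA-rate model, fitted per language on correct-trial
means, replaces language/block with the posterior-mean correct-choice
drift per block (broadcast to participants under pooled fitting — the
alignment is a package convention, as is averaging posterior means over
stimuli). Random structure is a participant intercept plus slopes on
each time term, uncorrelated by default to aid convergence at desk
scale (a flag restores the full covariance); estimation is maximum
likelihood with BOBYQA. P-values use the normal approximation by
default with Satterthwaite optional — at hundreds of observations per
participant the two agree closely.

The same Wald-versus-Satterthwaite choice applies to the accuracy GLMM
(logistic, Type III Wald chi-square via `car::Anova`) and the log-RT
LMM. The 3-SD log-RT screen is applied within participant x language x
block — language included because the two language conditions are
separate sessions — and drops strictly-beyond-3-SD trials only; it is
not idempotent, which the report makes visible. RT tails are trimmed at
floor(1% of n) per side within participant x language before race-model
fitting, ties broken by stable input order.

# Error-pattern analysis

Confusion matrices are row-normalized per participant x language x
block, with zero-trial rows kept missing rather than imputed as zeros.
Acoustic similarity matrices are -1 times the Euclidean distance between
talkers over the six features, z-scored across talkers by default
because the features live on incommensurate scales (Hz vs. percent vs.
dB); `standardize = FALSE` reproduces raw-unit distances. The reliance
statistic is Spearman's rank correlation (average-rank ties) between the
12 off-diagonal confusion cells and the corresponding symmetric ASM
entries — the diagonal is excluded because only the error pattern is of
interest. The language contrast is summarized per participant (mean rho
per language) with mean ± SEM descriptives and a paired Wilcoxon
signed-rank test — a nonparametric choice made because the emulated
contrast is reported descriptively in the field and rho is bounded. The
acoustic-variance check between the two talker sets is a two-sample
Mann–Whitney test on the 6 pairwise distances per language.

# Numerical choices and degenerate inputs

* All first-passage quantities are computed in log space; survival uses
  `log1p(-exp(...))` with the two log-Phi terms, returning `-Inf` when
  cancellation would drive it non-positive.
* Offsets are bounded at 99.9% of the per-stimulus minimum RT so decision
  times stay strictly positive throughout sampling.
* Empty stimulus-by-block cells produce a warning and prior-dominated
  posteriors; all-correct behavioral data raise a separation error
  naming the degenerate condition; zero-variance features error under
  standardization; a fully blink-masked trace errors (it should have
  been rejected); a constant EA covariate is a rank-deficiency error.
* Chains, generators and pipelines are reproducible from a single
  integer seed; stage seeds are derived by fixed offsets.

# Problem sizes used by the validation suite

The acceptance tests run: the race-equivalence study at n = 50,000 exact
samples and 100,000 diffusion paths (0.1 ms steps); the recovery study
at 400 trials per stimulus per block, 20 replicates; the GCA calibration
at 200 replicates of an 8-participant, 25-bin, two-block null design;
and one full default study (24 participants, 9,600 trials, 9,600 pupil
traces) through every stage. These sizes are the package's choices for a
thorough desk-scale validation; all scale up without code changes.

# Known limitations

* The race model omits starting-point bias, across-trial drift
  variability, and inhibition between accumulators, and fits pooled
  rather than hierarchical participant effects by default.
* The marginal-posterior shrinkage along the offset ridge (a few percent
  at 400 trials/cell) is inherent to the model, not removable by longer
  chains; comparisons across blocks and languages are unaffected because
  the geometry is shared.
* The pupil generator's amplitude-drift link is deterministic, which
  (as discussed) forces a choice between emulating the accuracy
  interaction and the pupil-gap trajectory.
* Blink *detection* is out of scope: the mask is an input column, as
  produced by eye-tracker vendor software.
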