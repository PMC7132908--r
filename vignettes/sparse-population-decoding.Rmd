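---
title: "Methods: psychometrics and sparse population decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: psychometrics and sparse population decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsecode)
options(sparsecode.quiet = TRUE)
```

`sparsecode` links two measurements of the same behaviour: how quickly a
mouse can extract the orientation of a briefly flashed grating in a
two-alternative forced-choice (2AFC) task, and how much information about
that orientation is present in the spike counts of primary visual cortex
(V1) neurons over the same time scale. This vignette is the package's own
account of the models and the choices behind them.

## The psychometric model

Performance as a function of stimulus strength $s$ (duration in ms, or
contrast) is modelled as a logistic with a lapse:

$$P(s) = \gamma + (1 - \lambda - \gamma)\,
  \frac{1}{1 + e^{-(s - m)/\omega}}$$

with $\gamma$ the guessing rate (fixed at 0.5 for 2AFC), $\lambda \in
[0, 0.5)$ the lapse rate (the shortfall of the upper asymptote), $m$ the
stimulus strength at half-maximum performance and $\omega$ the width over
which performance rises. On the duration axis the fitted $m$ is the
threshold integration time $\tau$; on the contrast axis it is the
threshold contrast $\upsilon$.

Fitting is constrained maximum a posteriori (MAP) plus MCMC: a binomial
likelihood per stimulus level, a Beta(1.2, 12) prior on $\lambda$, and
flat priors on $m$ and $\omega$ over the observed stimulus range.
$\omega$ is bounded below at $10^{-3}$ of the range so the fit cannot
collapse onto a step function. Zero-contrast trials carry no stimulus
information and are dropped from the level table on the duration axis;
data with fewer than two distinct levels, or with no response variation,
are flagged `degenerate` and never fitted.

The sampler is an adaptive random-walk Metropolis: componentwise
proposals during warm-up (scales tuned toward 35% acceptance), then joint
multivariate-normal proposals whose covariance is the warm-up posterior
covariance scaled by $2.38^2/d$. The joint phase matters because $m$,
$\omega$ and $\lambda$ are strongly correlated when the sampled durations
only just reach the plateau. Defaults are 4 chains of 5000 draws after
1000 warm-up iterations; convergence is checked with split-$\hat R$
(flagged above 1.05, results still returned). Credible intervals are the
2.5/97.5 percentiles of the marginal posteriors. Point estimates are MAP
(from `optim` under the same posterior, multiple starts); the posterior
mean would be an equally defensible convention, MAP was chosen because
the downstream "most likely estimates" of the balanced average subject
are computed per resample where a full posterior would be wasteful.

Two definitions of the **total integration time** $T$ ("duration at 90%
of maximum performance") are possible: relative to the above-chance range,
$P(T) - \gamma = 0.9\,(P(\infty) - \gamma)$, which has the lapse-invariant
closed form $T = m + \omega \ln 9$, or on the absolute scale, $P(T) = 0.9
P(\infty)$. The range-relative form is the default (`relative = TRUE`)
because it does not conflate the speed of integration with the lapse
rate; the absolute form is available behind the switch.

Reaction-time filtering keeps trials in $[0.05, 5]$ s, boundaries
inclusive; trials faster than 50 ms would require impossible motor
speeds and slower than 5 s indicate disengagement. Binomial confidence
intervals are exact Clopper-Pearson (Beta quantiles); differences of
proportions use the Agresti-Caffo add-one adjustment. The **average
subject** draws the minimum per-subject trial count from every animal
without replacement, refits, and repeats 1000 times, so each animal gets
equal weight regardless of how many trials it performed.

## Unit characterisation

Spike counts are extracted in half-open, onset-aligned windows; the
default analysis window is 0-500 ms, which in the short-stimulus design
covers every stimulus plus response latency and tail. Response
probability is $P(\text{count} \ge 1)$ per unit and condition in the
window spanning the stimulus plus 100 ms; the responsive fraction is the
per-trial fraction of simultaneously recorded units with at least one
spike.

Orientation selectivity uses the doubled-angle vector sum: $\mathrm{OSI}
= |\sum_k R_k e^{2i\theta_k}| / \sum_k R_k$ (one minus the circular
variance), with the preferred orientation as half the resultant angle.
The ratio form $(R_{pref} - R_{orth})/(R_{pref} + R_{orth})$ sits behind
`method = "ratio"`. No baseline subtraction is applied by default; the
vector-sum form is bounded, standard, and robust for the low rates at
hand. Errors are leave-one-trial-out jackknife standard errors (the SD
of replicates inflated by $\sqrt{(n-1)^2/n}$, circular SD for the
preferred orientation).

Fast- versus regular-spiking classification is k-means ($k = 2$, 50
restarts) on standardised spike width and log firing rate (rates span
more than two decades, so the log is essential); the narrower-waveform
cluster is labelled fast. Arousal is read from pupil size alone: the
trace is median-filtered over 1 s, z-scored over the session, and a
trial is high-arousal when the mean $z$ within its count window exceeds
0 (ties, including a constant trace, go to low). Trial-mean $z$ over the
count window was chosen over epoch-level assignment because it is
well-defined for arbitrary trial spacing.

## The decoding protocol

Each unit's spike count is regressed on the left/right label with binary
logistic regression. Zero-contrast trials are excluded from training
— they have no correct orientation — and from the accuracy; the decoder's
left/right prediction split on them is reported as a separate
diagnostic. Trials are split 70/30 into training and test sets,
stratified by (orientation, contrast, duration) so every condition with
at least two trials appears in both sets, and the split is repeated 100
times. A unit is a **consistent predictor** when its slope is
significant (two-sided Wald $p < 0.05$) with a stable sign in at least
70 of the 100 splits; the stable-sign requirement operationalises
"predicts the same orientation no matter which trials are included".
Performance is the mean test accuracy over splits; predicted probability
exactly 0.5 breaks toward "left", deterministically.

Numerical care: complete separation makes the unpenalised fit's Wald
test collapse (Hauck-Donner), so separation (detected by non-convergence,
runaway coefficients, or near-zero deviance) falls back to a
ridge-penalised IRLS with penalty $10^{-4}$ on the slopes, flagged in
the result, and the slope p-value on that path comes from a
likelihood-ratio test instead. The population decoder uses all
simultaneously recorded units as features under the same protocol and
takes the same ridge path whenever trials do not exceed units by at
least 10.

The false-positive rate of the consistency rule on null units is not an
analytic quantity (the 100 splits overlap heavily); it is measured by
simulation in the test-suite and by `calibration_report()` on an
uninformative population, where it stays below a few percent.

## Virtual populations

For each unit we tabulate its observed spike counts by stimulus
condition. A virtual session of size $N$ draws $N$ units from the pool
of consistent predictors with replacement, simulates balanced left/right
trials of one condition by sampling each unit's count from its own
response multiset for that condition (nonparametric — no refit Poisson),
and combines units as independent regressors. The combination rule is
the sum of per-unit log-odds, intercepts included — the natural
composition of independent evidence; a per-unit majority vote is
available behind `combine = "vote"` for sensitivity analysis. Curves
report the median and 2.5/97.5 percentiles of accuracy across 1000
resampled sessions per size; the required population size is the
smallest $N$ whose median reaches a behavioural target, with an interval
from the resample level. Both the across-resample interval and the
across-condition spread are accessible (the curve object retains the
full accuracy matrix).

Two caveats are inherent to the method, not to this implementation.
First, virtual sessions resample the same response tables the decoders
were fit on, so with small per-condition tables even truly uninformative
units carry a finite-sample optimism into the pooled accuracy; it decays
as tables grow (the test suite demonstrates both regimes). Second,
sampling units independently destroys trial-to-trial co-fluctuations, so
the curves answer "what could independent units of this quality
support", which is why the within-condition shuffle control exists:
`shuffle_within_condition()` permutes counts among trials of identical
(orientation, contrast, duration) per unit, preserving every per-unit
marginal while destroying noise correlations.

The sensory/cognitive noise models translate a behavioural target into a
decoder target. Under sensory noise the decoder must match behaviour
directly. Under cognitive noise a random fraction of trials equal to the
lapse rate is answered at chance after perfect sensory processing, so
the decoder must reach $(P_{behav} - \lambda/2)/(1 - \lambda)$ on the
remaining trials — always at least as hard, hence the requirement is
non-decreasing in $\lambda$.

## What the synthetic data emulate

The generator exists so that every stage is testable without recordings.
Behaviour is exact: Bernoulli responses from the closed-form observer,
lognormal reaction times, and configurable fast/slow outliers to
exercise the filters.

Spike counts are Poisson conditional on a per-trial lognormal gain
(doubly stochastic), which buys over-dispersion and a single
noise-correlation dial (`shared_gain_sd`; 0 gives independent units).
Per unit, the expected count in a window is

```
gain_t * (baseline * eff(window) +
          amplitude * contrast_gain(c) * tuning(theta) * overlap(window, d))
```

with a Hill contrast gain centred at the behavioural threshold contrast
(0.15), a doubled-angle von Mises tuning curve, and an evoked interval
running from a 50 ms latency to 100 ms past stimulus offset.

The ongoing (stimulus-independent) intensity is deliberately
non-homogeneous: a low tonic rate plus an elevated late component
(default 300-600 ms after trial onset, gain 8). This is the minimal
structure that can make a unit silent in short stimulus-locked windows
on most trials while still giving a much larger fraction of units at
least one spike over the full 500 ms window — a time-homogeneous Poisson
process cannot do both, because $P(\ge 1$ spike in $w)$ would then be
concave in $w$. Physiologically the late component stands in for
recurrent network activity that outlasts brief stimuli.

Only a fraction of units (`informative_fraction`, 0.25 in the frozen
`v1_default` preset) respond to the brief ±45° flashes in an
orientation-dependent way; their preferred orientations cluster near the
discriminanda and their evoked amplitudes are drawn from their own
lognormal. The remaining units respond with an untuned transient of
matched mean drive — so setting the informative fraction to 0 pins
single-unit decoding at chance by construction, and 1 with large
amplitudes drives it toward 1. For long characterisation gratings
(duration ≥ 500 ms) all units express their tuning, which is what the
orientation-tuning stage measures. Arousal, when simulated, is a slow
two-state process (dwell times of seconds) driving pupil size and a
common firing gain, so the z-score split can be exercised end to end.

The `v1_default` preset was calibrated once against the published
population statistics — the responsive fraction in the 0-500 ms window,
the bound on per-trial spike probability at the strongest condition, the
prevalence of consistent predictors and their mean decoding performance
— and then frozen; sessions have 30 units and 50 trials per condition
cell over the study grid {0, 0.15, 1} × {50, 100, 150, 200 ms}. The
preset targets those sparsity and decodability statistics, not the full
firing-rate distribution: its session rates sit at the sparse end of the
published 0.2-80 Hz range, and the fast/regular cluster means in its
metadata are not tuned to the published cluster centroids (the waveform
classifier is validated on dedicated synthetic clusters instead).
Passing tests on this preset show the pipeline measures what the
generator encodes; they cannot show that real V1 responses satisfy the
generator's assumptions (Poisson-given-gain counts, a single shared gain,
piecewise-constant intensities).

## Problem sizes and reproducibility

Every stochastic operation takes an explicit integer seed and is
bit-reproducible under it; pipeline stages derive independent
sub-streams from one master seed. The shipped analyses use problem sizes
chosen to keep Monte-Carlo error well inside the tolerances they are
compared at: 8 duration levels × 2000 trials for psychometric recovery
(20 replicates), 15-20 sessions (450-600 units) for the preset's
decoding statistics, and 150-1000 resamples per population size for the
virtual-population curves. The default split protocol is always 100
splits of 70/30.

## Data flow and formats

All tables are plain delimited text with named headers (comma default,
tab accepted): trials, spike events, presentations, unit metadata (with
";"-joined waveform and ISI-histogram vectors) and arousal traces. Times
are in seconds, durations in milliseconds, depths in micrometres.
Recording depths shallower than 400 µm are superficial (L2/3), deeper
than 450 µm deep (L5/6); the 400-450 µm gap between the two published
definitions is labelled ambiguous and excluded from layer contrasts.
Chronic-probe duplicates are detected on the same electrode and depth on
consecutive days (transitively closed) when both the mean waveform and
the ISI histogram correlate above Pearson r = 0.95, correlating the
stored vectors without normalisation; only the earliest-day unit is
kept. Every filtering or dropping step logs its before/after counts.

## A small worked run

```{r pipeline, eval = FALSE}
res <- run_pipeline(list(seed = 5, out_dir = tempfile("sparsecode_"),
                         n_sessions = 2L, n_splits = 50L,
                         behavior_trials_per_level = 100L,
                         n_resamples = 50L))
res$summary
```

The pipeline writes one CSV per stage (trials, psychometric fits,
per-unit characterisation, decoding summary, population curve,
required-N estimates, shuffle check) plus a consolidated `summary.csv`
whose every number is copied from a stage file, never recomputed, and a
copy of the configuration used.
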