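---
title: "EEG information transfer, multifractal and spectral features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG information transfer, multifractal and spectral features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itmeeg)
```

itmeeg extracts three families of quantitative features from multichannel
resting-state EEG and couples them to a small-cohort, out-of-sample
prediction pipeline for cognitive subscores.  This vignette is the
package's account of the science: the models, their assumptions, the
tunable parameters and the reasoning behind every numerically consequential
choice.

## The data model

A recording is a leads x timepoints voltage matrix with a sampling rate
(`eeg_record`), in microvolts throughout.  The unit matters: the
within-lead information transfer constant takes a logarithm of |dV|, so
rescaling the signal shifts the statistic.  Both file readers (EDF via
`read_edf()`, delimited matrices via `read_matrix()`) convert to uV on
ingestion, and no re-referencing, filtering or artifact rejection is
applied — the package analyses every lead as recorded, deliberately
modelling the "all leads in, noise and all" regime of pragmatic clinical
EEG.

Time is 0-based and epoch windows are half-open `[start_s, end_s)`, so a
30 s window at 250 Hz is exactly 7500 samples; this removes the
off-by-one ambiguity that plagues second-based epoching.  The study
protocol cuts two 30 s epochs per subject — `[90, 120)` s to train and
`[210, 240)` s to test — far enough apart to be distinct states of the
recording but close enough to share slow subject-level structure.

## Information transfer constants

Treating the voltage trace as an information-transfer device postulates
that voltage increments scale with the time interval, `|dV| ~ dt^kappa`.
Per timepoint,

    kappa(t) = log |V(t + dt) - V(t)| / log(dt_ms)

with `|dV|` in uV and the lag expressed in **milliseconds**.  The unit
choice in the denominator is forced: with the lag in samples a 1-sample
delay gives `log(1) = 0`, yet 1-sample (4 ms at 250 Hz) features are among
the most informative in practice.  In milliseconds the denominator is
`log(4)` there, and the package rejects only the truly singular case of a
lag of exactly 1 ms.  The absolute value inside the numerator is likewise
the only reading under which the statistic is real-valued.

Timepoints with `|dV| = 0` are excluded and counted (`n_valid` vs
`n_total`); the segment summary is the arithmetic mean over valid points —
never the bare sum, and never a silent zero when no point is valid (an
`NA` sentinel with a warning instead, median-imputed later by the
modeling stage from training data only).

The between-lead ratio for an ordered pair (source, dest) at a shared lag,

    kappa_itcr(t) = log |dV_source(t)| / log |dV_dest(t)|,

measures relative information flow between scalp sites.  The lag cancels
from the value and only aligns the increments.  Two exclusion guards
apply: either increment being zero, and `| log |dV_dest| | < 1e-8` —
`|dV_dest|` exactly 1 uV zeroes the denominator, and the guard is counted
in the exclusion bookkeeping rather than silently absorbed.  Pairs are
**ordered**: information flow is directional and `kappa_itcr(a, b)` is not
constrained to be the reciprocal of `kappa_itcr(b, a)`.  For L leads and D
lags this gives `L*D` within-lead plus `L*(L-1)*D` between-lead features —
20,480 for 64 leads with five lags per grid, which is why the modeling
stage operates on a 10-lead scalp-covering subset (`study_leads()`,
500 features).

Delay grids are fully configurable.  The defaults are `{1, 2, 4, 8, 16}`
samples within-lead (a doubling ladder, 4-64 ms at 250 Hz) and five
integer lags log-spaced over `[1, 1000]` samples (`{1, 6, 32, 178, 1000}`,
4 ms to 4 s) between leads, spanning both the synaptic-scale and the
slow-envelope ends of cortical interaction timescales.

## Multifractal detrended fluctuation analysis

MF-DFA asks how the detrended fluctuations of the integrated signal grow
with window size, moment order by moment order.  The pipeline is the
standard one: profile `Y(i) = sum_{k<=i} (x_k - mean x)`; windows of `s`
samples taken from both ends (`2*floor(N/s)` windows, so the tail beyond
the last full window is never discarded); least-squares polynomial
detrending of degree `m`; per-window variances `F2`; and

    F_q(s) = { mean(F2^(q/2)) }^(1/q),   q != 0
    F_0(s) = exp( mean(log F2) / 2 )

with `h(q)` the least-squares slope of `log F_q(s)` on `log s`.  Mass
exponents follow as `tau(q) = q h(q) - 1`, and the Hoelder (singularity)
spectrum by Legendre transform, `alpha = dtau/dq` via central differences
on the q grid and `f(alpha) = q alpha - tau`.  Central differencing drops
the two endpoint orders, so the spectrum lives on the interior grid; the
four per-lead summaries — mean, minimum and maximum Hoelder exponent and
spectrum width — are taken over those interior `alpha` values, the mean
being their arithmetic mean.

Defaults: `q = -5..5` in integer steps (11 orders; 0 and 2 mandatory so
the q = 0 limit and the classical DFA exponent are always available), 12
log-spaced integer scales in `[16, N/8]` (duplicates after rounding
dropped — log-spacing collides at small N), linear detrending (`m = 1`).
Scales are capped at N/4 because fewer than four windows per end makes
the window-mean unstable.  A window with numerically zero residual
variance (an exactly polynomial stretch) is floored at 1e-30 with a
warning so negative moments stay finite; this arises for degenerate
synthetic inputs, not EEG.

Validation rests on two closed-form oracles: fractional Gaussian noise
(monofractal, `h(2) = H`, narrow spectrum — width stays below 0.35 at
n = 7500) and the binomial multiplicative cascade, whose exact
`h(q) = 1/q - ln(p^q + (1-p)^q)/(q ln 2)` the estimator tracks within
±0.1 across the full q range.  The test suite enforces both, plus exact
agreement (1e-10) of the q = 2 path with an independently coded naive DFA.

## Band-power spectra

The spectral family is a raw periodogram: demeaned signal, optional
split-cosine taper (`taper_fraction`, default 0 — whether the original
analyses tapered is unknowable, so the choice is exposed rather than
buried), ordinates `|X_k|^2 / N` at the positive Fourier frequencies.
No Welch averaging or smoothing: band power sums raw ordinates, and a
scale-equivariant tree learner downstream is indifferent to the fixed
normalisation.  Parseval's identity is asserted in the tests to 1e-8.

Band edges are exactly the conventional clinical values used throughout
this line of work: delta 0.1-4, theta 4-7, alpha 8-14, beta 16-31, gamma
32-50 Hz, as **closed** intervals.  Two consequences are documented
rather than "fixed": the 7-8, 14-16 and 31-32 Hz gaps belong to no band,
and delta and theta share the 4 Hz edge, so an ordinate landing exactly
on 4 Hz contributes to both.  On a 30 s epoch the Fourier spacing is
1/30 Hz, so the lowest ordinate inside the delta band sits at 0.133 Hz.

## The CART prediction pipeline

Features from the training epoch feed a regression tree per subscore;
the pruned tree then predicts the subscore from the *test*-epoch features
of the same subjects, and the report is the Pearson correlation between
predictions and actual scores with its exact t test
(`t = r sqrt(n-2) / sqrt(1-r^2)`, df = n-2, two-sided).

The tree learner is classical CART with fully pinned-down conventions:

* greedy variance-reduction splits; candidate thresholds at midpoints of
  adjacent distinct values; `x < threshold` goes left, ties between
  splits broken by lower feature index then lower threshold — every fit
  is bit-reproducible;
* `minsplit = 4`, `minbucket = 1`: with 12 subjects any stricter floor
  forbids splitting altogether;
* weakest-link cost-complexity pruning computed at fit time, indexed by
  `cp = alpha / SS0`;
* seeded 10-fold cross-validation: folds are a uniform random partition,
  each fold's tree is pruned at the geometric mean of adjacent master-cp
  values and scored out-of-fold; the standard error of the CV error is
  estimated from the per-observation squared prediction errors
  (`sd(e_i) * sqrt(n) / SS0`);
* the **1-SE rule**: the selected cp is the largest (smallest tree) whose
  CV error is within one standard error of the minimum — at n = 12,
  parsimony is the only defensible prior.

A tree pruned to its root predicts a constant; the correlation is then
undefined and the report row carries an `NA` with a `degenerate` flag —
reported as non-significant, never coerced to zero (except in
shuffled-score *summaries*, where a constant predictor is counted as
|r| = 0 because it carries no linear association).  Missing feature
values are imputed with training-set medians before fitting, so no
surrogate-split machinery is needed.

The test suite holds the learner to an exhaustive-search oracle: on 100
random 12 x 6 tables the fitted trees match a separately coded naive
greedy search node-for-node, and the pruning sequences match a
brute-force weakest-link enumeration.  rpart, under matched controls,
reproduces the in-sample fitted values.

## The synthetic cohort generator

`gen_cohort()` emulates the study's data shape — by default 12 subjects,
64 leads at 250 Hz, 5 minutes — as 1/f-like background (spectral
synthesis, configurable exponent) plus one sinusoid per canonical band
per lead, with three kinds of planted structure:

* **persistent subject latents**: a driven (lead, band) pair's amplitude
  is `osc_amp * (0.2 + 2.8 u)` with `u ~ U(0,1)` drawn once per subject,
  constant across the whole recording.  Persistence is what makes a
  two-epoch train/test design meaningful: without it, out-of-sample
  correlation would be impossible by construction;
* **directed coupling**: a destination lead rebuilt as
  `gain * lag(source) + noise`, with zero-lag cycles rejected.  With
  unit gain, zero lag and zero noise this plants the exact
  `kappa_itcr = 1` identity;
* **driven scores**: a declared subscore equals `effect * u` plus
  Gaussian noise (`score_noise_sd`); undeclared subscores are pure
  noise.

All generators (`gen_powerlaw_noise()`, `gen_fgn()` by circulant
embedding, `gen_binomial_cascade()`) are bit-reproducible under a
mandatory seed and return their ground truth (H, p, theoretical h(q),
latents, coupling graph) alongside the data, so parameter-recovery tests
never re-derive what the generator already knows.

What the generator does **not** emulate: eye-blink/EMG artifacts,
electrode impedance failure, volume conduction, non-stationary state
changes, or physiologically realistic cross-frequency structure.  Passing
tests therefore demonstrate that the estimators recover *planted*
structure of the right kind and magnitude — they do not certify
performance on clinical recordings, where all of the above conspire
against any feature family.

Problem sizes in the test and acceptance suites are chosen to make each
check sharp at interactive cost: 7500-sample epochs wherever a spectral
or scaling property is asserted (the study's own epoch length),
2^13-sample cascades over 20 seeds for the multifractal oracle, 100
random tables for the tree oracle, and a 12-subject, 10-lead cohort with
a strong alpha-band driver (effect 3, score noise 0.1) plus a 50-seed
shuffled-score null for the end-to-end recovery check.

## Known limitations

* The per-instant `kappa(t)` is a noisy point statistic; only segment
  means are reported, and their sampling variability is not modelled.
* MF-DFA width is biased upward at short series length; the monofractal
  /multifractal threshold (0.35 at n = 7500) is length-specific.
* With n = 12 subjects the CV-error estimate is itself noisy; the 1-SE
  rule absorbs some but not all of that variance, and out-of-sample
  correlations from such cohorts carry wide confidence bands
  (df = 10 for every t reported).
* The EDF writer emits a minimal continuous-EDF subset (1 s records,
  integer sampling rates); EDF+ annotations are ignored on read.
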