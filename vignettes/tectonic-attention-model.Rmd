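---
title: "The tectonic accumulation model: methods, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tectonic accumulation model: methods, defaults, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tamrt)
```

## The model and its assumptions

The tectonic account treats selective attention as two concurrent
processes.  When a target tone is presented, its perceptual representation
is excited while the memory representations of the other stimuli — the two
currently non-presented targets and the distractor set — are inhibited.
All activation trajectories share one functional form, an inverse logistic
raised to the exponent 10, differing only in their asymptotic bound: +1 for
the perceived target, −1 for each remembered target, and −3 for the pooled
distractor trace (a single inhibitory slope serves all distractors of a
condition, which keeps the distractor side comparable in weight to the
three-target side).  A remembered target shares the slope of the same
target when perceived: perceived and remembered traces of one stimulus
differ only in direction.

Evidence for the presented target is the log ratio of the excitatory
activation (offset by the constant 6.0, which keeps the ratio inside the
range of the stopping rule) to the combined inhibitory activations plus the
same constant.  The evidence starts near zero — exactly
`log((6 + 2^-10)/(6 − 5·2^-10)) ≈ 0.000977` at `t = 0`, independent of the
slopes — rises strictly monotonically, and saturates at `log 7 ≈ 1.946`.
A response is emitted when evidence reaches the stopping rule `β = 1`, and
the number of accumulation cycles needed is the predicted RT.

Trial-to-trial variability has a single scalar source per trial, `x`,
shared by all four slopes:

`slope = logistic(start + swell · x) · 0.023`

The *start* parameters set the baseline level of each slope (the long-term
memory contribution); the *swell* parameters set how strongly the trial's
stochastic state perturbs it.  The multiplicative constant 0.023 bounds all
slopes and replaces additional free scale parameters.

### Time base and solvers

One accumulation cycle is identified with one millisecond, because the
estimation stage substitutes observed RTs (in ms) directly for the
accumulation time.  The crossing time is solved two ways: a continuous
bisection (the default — the evidence function is strictly increasing, and
a smooth solution is needed inside optimisation) and a literal integer
cycle scan, retained as an oracle; the two agree within 1 ms, which the
test suite verifies on 1000 random slope sets.

## Model variants and the two-stage fit

Estimation is per participant and sequential.  Stage one fits the six
baseline-condition parameters (`tstart_1..3`, `tswell`, `dstart`, `dswell`)
by Nelder–Mead on the objective

`objFunc = Σ_h (β − E(T_i(h), rt_h))²`

— the evidence evaluated at each observed correct-target RT.  Before the
fit, each cell's noise values are rank-paired to the observed RTs (smallest
`x` to the shortest RT, ties stable in trial order).  The pairing direction
is fixed; the swell signs are free, so estimation resolves whether small
`x` speeds or slows a trial.  Stage two differs by variant:

* **inhibition-only** (9 free parameters): `dstart` re-fit in each
  condition, everything else carried from baseline;
* **excitation-only** (15): the three `tstart`s re-fit per condition;
* **RP** (7): per-participant OLS regression of the inhibition-only
  `dstart` estimates on condition-average distractor-trial (RP) amplitude;
  the linked `dstart` replaces the per-condition estimates and the
  remaining five parameters are re-estimated at baseline;
* **PN** (9): the analogous per-target links from target-trial (PN)
  amplitude, with `tswell`, `dstart`, `dswell` re-estimated at baseline.

The amplitude is always the regression *predictor* and the model parameter
the response, so a linked parameter is `intercept + coefficient ×
amplitude`.  The backfit stage then inserts the final parameters and each
trial's `x` into the slope equations and solves for the threshold-crossing
time — by monotonicity, the time minimising `(β − E(t))²` — giving the
per-trial predicted RT.

### Numerical choices in the optimiser

Baseline fits start at `tstart = dstart = 0`, `tswell = dswell = 0.5`, with
5 restarts (the first unjittered, the rest jittered with SD 0.25), Nelder–
Mead relative tolerance 1e−8, up to 2000 iterations.  One-dimensional
per-condition `dstart` refits use golden-section search on [−12, 12]
(a simplex is degenerate in one dimension); the objective is the same.

Because the objective evaluates parameters only *at the observed RTs*, it
admits degenerate optima that a practitioner would reject on sight.  Two
families appear in practice: saturation optima, in which start/swell pairs
drive the slope logistic far outside its responsive range so that slopes
are pinned at 0 or 0.023 for most trials, and rank-inconsistent optima,
whose implied noise-to-RT mapping contradicts the ascending/ascending rank
pairing the fit itself was conditioned on.  Both fit well in-sample and
extrapolate pathologically (crossing times orders of magnitude beyond the
simulation horizon, or inverted noise effects in linked conditions).  A
restart is therefore *admissible* only if its parameters (a) reproduce
every fitted trial within the 5000-cycle horizon the forward simulator
enforces, (b) keep every realised slope argument `|start + swell·x| ≤ 12`
on the fitted trials (beyond `logistic(12)` a parameter has no local effect
on any trial, so no expressiveness is lost), and (c) map ascending `x` to
non-decreasing predicted RTs within each target, per cell — including the
cells the parameters will serve after linking.  Admissible candidates
compete on a selection score that evaluates the whole sequential procedure
a baseline candidate seeds (its own objective plus each filtering cell's
objective after a cheap 1-D `dstart` refit); the score is deliberately
variant-independent so that every variant proceeds from the same baseline
estimates — the variants are identical models in the baseline condition.
If no restart is admissible, the restarts are repeated under a smooth
quadratic barrier on slope-argument excess; failing that, the best fit is
kept but flagged unconverged.

The backfit itself never clips: if a fitted trial's crossing falls beyond
the horizon (possible for extreme noise values under fitted rather than
generative parameters), the bisection bracket is extended until the
crossing — which is guaranteed to exist — is found exactly.

## EEG feature extraction

Epochs are single-channel Fz series at 250 Hz covering −100 to 696 ms (200
samples).  Processing is: baseline correction by the mean of the
pre-stimulus samples (times in [−100, 0) ms), artifact rejection at ±100 µV
on the corrected epoch, and the slow-wave amplitude as the mean over the
[400, 600) ms window — half-open so the 600 ms sample is not double-used,
giving exactly 50 samples at the 4 ms step.  Condition-average RP (PN) is
the mean over valid distractor (target) trials.

Single-trial RP-noise is the rescaled per-trial amplitude.  The rescaling
constant is implemented as 1/SD of the participant-condition pool
(`rescale_noise()` default), with a centre-and-scale mode also available.
The fitting and simulation pipelines use the centred mode by default: the
per-trial noise is the momentary *fluctuation* about the condition-mean RP
level, because the mean level itself enters the model through the amplitude
link.  Leaving the mean in the noise series would double-count it — and
shift the effective target-excitation parameters per condition, a component
no variant can represent, since `tstart` is estimated only at baseline.

## The synthetic experiment and its ground truth

The generator reproduces the source design: 4 conditions × 300 trials (150
target at 50 per target stimulus, 150 distractor), targets 962/1000/1040 Hz
in every condition, distractor sets 1020 (baseline), 982/1020/1060,
954/1020/1090, 929/1020/1120 Hz, inter-onset intervals uniform on
1450–1600 ms, 11 participants.

Ground-truth defaults were chosen once, as the study conditions the
package's tests exercise:

* condition-mean RP amplitude 2.0 / 1.5 / 1.0 / 0.5 µV with trial SD
  1.0 µV — a monotone decrease of the frontal slow wave with distractor
  salience; configuration defaults, not empirical values;
* `tstart = (−1.35, −1.45, −1.55)`, `tswell = dswell = −0.22`, and a
  per-participant linear link `dstart = intercept + coefficient ×
  amplitude` with intercept ≈ −1.85 and coefficient ≈ +0.5 µV⁻¹ (all
  jittered across participants).  These place deterministic (x = 0)
  baseline RTs near 700 ms and give condition means of roughly 620 to
  840 ms with trial SDs of 110–160 ms — the scale of the source
  experiment.  Negative swell makes small noise values produce steep
  slopes and fast trials, consistent with the fixed rank-pairing
  direction;
* target-trial (PN) amplitudes −1.0 to −1.6 µV across conditions, so the
  PN-linked variant is well-defined even though the truth never varies
  target excitation;
* error rate 5% (correct flags drawn independently); distractor trials
  carry no RT.

RTs are generated purely through the model — no measurement noise is added
— so the forward-simulation/backfit roundtrip is exact and every pipeline
stage can be validated against known truth.  A master seed fans out into
independent sub-seeds for design, parameters, amplitudes and RT noise, and
within fitting one sub-seed per participant, so components reproduce
independently and model variants share identical noise assignments.

### What the generator does and does not emulate

It emulates the design structure, the monotone RP pattern, the RT scale,
and the single-scalar-noise generative process of the model itself.  It
does not emulate: real EEG spectra or artifacts (epochs, when requested,
are white background noise plus a boxcar slow wave), sequential effects,
fatigue or learning, lapses and fast guesses, or any deviation of human RT
distributions from the model family.  Passing tests therefore demonstrate
internal consistency of the pipeline — recovery of generative structure by
the estimation machinery — not the empirical adequacy of the model for
human data.

## Evaluation

Condition-level fit uses Vincentized distributions: each participant's RTs
are sorted and split into 20 consecutive bins (the first 5%, the second
5%, …; when n is not divisible by 20 the remainder goes one-each to the
earliest bins, a deterministic order-stable rule), bin means are averaged
across participants per quantile, and the group distributions are compared
on the density scale `P(i) = 50/(RT(i+1) − RT(i))`, i = 1..19.  The
chi-square statistic `Σ (P_obs − P_pred)²/P_pred` is referred to 17 degrees
of freedom (19 density cells minus two constraints); the construction is
isolated in one function (`chisq_quantiles()`) so the convention can be
swapped.  Trial-level fit uses the first four moments with population
(divide-by-n) denominators — mean, dispersion δ (the square root of the RT
variance), skewness, and excess kurtosis (the −3 term included) — tabulated
per cell as predicted minus observed.  Repeated-measures ANOVA on the
moment tables is standard statistics and out of scope; the tables it would
consume are produced.

## Known limitations

* The baseline cell alone weakly identifies the inhibitory pair
  (`dstart`, `dswell`); the admissibility screen and the sequential
  selection score remove the degenerate optima but cannot make the pair
  fully identifiable from one condition.
* The chi-square df convention (17 from 20 quantiles) is a documented
  choice, not a derived sampling distribution; the p-values are
  heuristic.
* Model discrimination between inhibitory and excitatory modulation is
  sharpest when generation and fitting share the noise series (the
  RP-noise route); with freshly sampled Gaussian noise the quantile
  mismatch of a 150-trial sample adds a comparable chi-square floor to
  both variants and can mask the ordering in single conditions.
* With fewer noise values than correct trials the pool is resampled with
  replacement (and the event logged); the source procedure leaves this
  case open.

## Problem sizes used by the tests

The acceptance-style tests run the full 11-participant, 4-condition design
(~150 correct target trials per cell, about 6300 pooled trials) for the
fully linked RP-model analysis, parameter recovery, and model
discrimination; solver agreement is checked on 1000 random slope sets; unit
tests use 1–3 participants.  These sizes match the source design while
keeping the default suite to about half a minute.
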