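---
title: "Decoding outcome valence from set-shifting LFPs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding outcome valence from set-shifting LFPs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`iedlfp` analyses bilateral intracranial local field potentials (LFPs)
recorded while a subject performs an intra-/extradimensional (IED)
set-shifting task: a nine-rule, two-alternative forced-choice task in which
a rule advances after six consecutive correct choices and fails after 50
attempts, feedback lasts 0.5 s, and the next trial starts 2.7 s after
feedback onset. The package covers the full chain — behavioural simulation,
LFP simulation, preprocessing, event-related spectral perturbation (ERSP)
statistics, a sliding-window multivariate discriminant of outcome valence,
and behavioural trial-transition statistics — so that every stage is
testable end to end without access to patient recordings, which are not
publicly available for this kind of study.

This vignette documents the models, the parameters that matter, the
numerical choices, and the places where a design decision was genuinely
open.

## The behavioural simulator

The task side is deterministic given the rule schedule: blocks end at the
first run of `criterion_run` (6) consecutive correct trials or at the
`max_trials_per_rule` (50) cap, which fails the session. The agent is a
deliberately simple monotone learner: on trial $t$ of a block,

$$P(\text{correct}) = p_\infty - (p_\infty - 0.5)\,e^{-\lambda (t-1)},$$

mixed with a lapse probability of answering at random. Reaction times are
log-normal in milliseconds, and trials following an error receive an
additive shift on the log scale (post-error slowing). Two refinements make
the simulated sessions structurally faithful to the task:

* the first trial of a reversal block is forced incorrect whenever the
  previous rule was learned (`force_reversal_error`, default on) — the
  agent, still applying the old rule, must err — which guarantees the
  "unexpected incorrect" expectancy class is populated;
* the first trial of the rules that introduce new on-screen objects
  (rules 3, 4, 6, 8 in the standard schedule) is labelled `novel`, and
  trials inside a run of at least six consecutive correct choices are
  labelled `familiar`.

`learn_rate = Inf` means instant learning ($P = p_\infty$ from trial 1),
which is how an idealised error-free agent is expressed; with any finite
rate the model starts each block at chance.

**Defaults.** `p_asymptote = 0.9`, `learn_rate = 0.5`, `lapse = 0.1` give a
mean consecutive-correct rate of about 77%, close to the published 76.3%
for this task. The memoryless learning curve cannot reproduce the published
consecutive-*incorrect* rate of about 41%: without error perseveration, the
probability of repeating an error tops out near 29% across the plausible
parameter range. We kept the deliberately simple model and note the gap; the
published rates themselves are recomputed exactly from the printed
transition counts (`transition_table_from_counts()`), not from simulation.
RT defaults (`meanlog = log(940)`, `sdlog = 0.45`, post-error shift 0.11
log-units) give a median near 0.94 s with a right-skewed interquartile
range, matching the scale of the reported medians.

## The LFP generator

Each channel is the sum of

1. $1/f^{\alpha}$ Gaussian background noise ($\alpha = 1$, RMS
   `noise_scale` = 5 µV by default), synthesized in the frequency domain
   with random phases — this gives the exact target spectrum for one FFT
   per channel;
2. fixed-phase line sinusoids at 50/100/150 Hz (2/1/0.5 µV defaults), so
   the notch stage has something real to remove;
3. Gaussian-windowed sinusoidal bursts
   $A\,e^{-(t-t_0)^2/2w^2}\sin(2\pi f (t - t_0) + \varphi)$ injected at
   `lock_event` onset + `center_latency` on the trials matched by a
   condition selector, scaled per channel by `channel_gains`.

Event times are snapped to the sample grid so epoching is unambiguous. The
noise stream depends only on the seed and each component's jitter stream on
a seed derived from (seed, component slot), so signals superpose linearly
across components — a property the test suite checks exactly.

The burst phase matters more than it looks: with $\varphi = 0$ (pure sine)
the burst is odd around $t_0$ and its mean over a 50 ms window centred at
$t_0$ is zero, so a broadband window-mean discriminant peaks a quarter
period *off* the injected latency. The lateralized preset and the
recovery experiments therefore use $\varphi = \pi/2$ (cosine), an ERP-like
deflection whose discriminable latency *is* `center_latency`.

**The lateralized preset** (`lateralized_sim_config()`) encodes the
two-system picture the package is designed to probe: a valence-independent
feedback response of 0.8 µV on the left channel and 0.3 µV on the right;
left-channel-only incorrect-trial components at 200 ms ("early") and
350 ms ("late"), both at 6.6 Hz — one theta period apart; and a
right-channel-only stimulus-locked novelty response. Condition-dependent
amplitudes are 8 µV against the 5 µV background: effect sizes deliberately
well above threshold, because the directional lateralization tests are
meant to verify the analysis code, not to estimate statistical power.

## Preprocessing

The chain is: 50/100/150 Hz notch → resample to 512 Hz → event-locked
epochs → baseline subtraction → z-scoring.

* **Notch.** Second-order IIR notch (standard audio-cookbook biquad), Q
  = 35 by default, applied forward–backward for zero phase. This
  `filtfilt` is done with odd-reflection padding of eight ringing time
  constants ($\tau = Q/\pi f_0 \approx 0.22$ s at 50 Hz), because the
  underlying single-pass filter routine does no edge handling of its own.
  Steady-state stop-band attenuation is below −90 dB; edge transients are
  confined to a fraction of a second at the recording boundaries.
* **Resampling.** Zero-phase Hamming-FIR anti-alias low-pass at 90% of the
  new Nyquist frequency, then cubic-spline evaluation on the new sample
  grid; the FIR is normalized to exact unity DC gain. (A packaged polyphase
  resampler was rejected after it showed a systematic ~15% gain error on a
  constant input.)
* **Epochs.** Windows are half-open `[start, end)` relative to the event,
  with the $t = 0$ sample on the post-event side; a six-second window at
  512 Hz is exactly 3072 samples. Trials whose window leaves the recording
  are dropped with a warning (the first trial of a session typically lacks
  the full 4 s pre-feedback history, exactly as in a real recording).
* **Normalization.** Per trial and channel, the mean of the baseline window
  (default −2000..0 ms) is subtracted; each channel is then z-scored by the
  mean and sample SD of a normalization pool. Pooling per recording
  (subject) and pooling per trial are both defensible conventions; the
  per-recording pool is the default because cross-subject comparability is
  the point of z-scoring here, and per-trial pooling is available via
  `pool = "trial"`.
* **Expectancy classes.** `expected_correct` (previous five trials all
  correct), `unexpected_correct` (first correct response to novel stimuli),
  `expected_incorrect` (first incorrect response to novel stimuli),
  `unexpected_incorrect` (first incorrect trial of a reversal block). When
  definitions overlap, precedence is `unexpected_incorrect >
  expected_incorrect > unexpected_correct > expected_correct` — the
  reversal-first reading; a trial matching nothing is `unclassified`, and
  the classes always partition the session.

## ERSP and permutation statistics

Time–frequency maps use complex Morlet wavelets on a 40-point log-spaced
3–100 Hz grid. The cycle schedule is the EEGlab-style `[3, 0.5]`
convention: 3 cycles at 3 Hz, expanding linearly with frequency to half of
the proportional maximum at 100 Hz. Wavelet filtering is done in the
frequency domain — the analytic Morlet at centre $f_0$ with temporal SD
$\sigma_t$ has spectrum $\exp(-2\pi^2\sigma_t^2 (f - f_0)^2)$ on positive
frequencies and zero on negative ones — which is exactly zero-phase and
needs one FFT per trial and channel. Samples within $3\sigma_t$ of an epoch
edge are reported as `NA`. Power is averaged over trials and expressed in
dB relative to the mean baseline-window power per frequency (default
−2000..0 ms, the pre-feedback interval; the time axis is decimated by 8 to
a 64 Hz map resolution).

Group contrasts randomly reassign trials to the two groups (sizes
preserved) `n_permutations` times (default 1000), recompute both group maps
from pooled single-trial power, and derive two-sided pixelwise p-values
with the `(1 + \#\{|\Delta_{null}| \ge |\Delta_{obs}|\})/(B+1)` estimator,
then Benjamini–Hochberg FDR jointly across all valid pixels of all
channels. Two practical notes:

* the permutation p floor is $1/(B+1)$; with pixelwise FDR over a full
  6 s × 40-frequency map nothing can survive correction unless a large
  fraction of pixels is active. `stat_time_range_ms` (the pipeline uses
  −500..1000 ms for feedback-locked contrasts) restricts which pixels enter
  the statistics — the map is still computed everywhere. Stimulus-locked
  contrasts end the statistics window at +600 ms, before the earliest
  selections (reaction times rarely fall below ~450 ms), so that
  feedback-locked activity — which is outcome-dependent, and outcome is
  correlated with novelty — cannot leak into the novelty contrast;
* "bootstrapping" and "permutation statistics" are used interchangeably for
  these comparisons in the literature this follows; the implementation is
  label permutation.

The theta-band trial-image view uses a zero-phase Hamming FIR band-pass
(3–8 Hz). The transition width is 2 Hz with the order capped at a third of
the epoch length: a 1 Hz transition at 512 Hz would need ~1690 taps, longer
than a third of a 3072-sample epoch, making the forward–backward pass
degenerate.

## The sliding-window discriminant

For each window centre $\tau$ (−200..600 ms in 10 ms steps, width
$N = 50$ ms), the trials × channels matrix of window-mean features is
formed — averaging commutes with a linear projection, so the mean feature
vector is sufficient — and a logistic regression with a small ridge penalty
on the spatial weights ($\lambda = 10^{-3}$, intercept unpenalized)
separates positive (correct) from negative (incorrect) outcomes. The ridge
stabilises windows with few minority-class trials and keeps collinear
channels finite; $\lambda \to 0$ recovers plain logistic regression.
Weights are oriented so positive-outcome trials project higher.

Performance per window is the ROC area (Az) of the pooled *leave-one-out*
held-out projections, with midrank tie handling. Each LOO refit starts from
the exact Newton step of the reduced problem — obtained in closed form by a
Sherman–Morrison rank-one downdate of the full-data Hessian — and keeps
iterating (fixed downdated Hessian, exact gradient, full IRLS as fallback)
until the penalized-likelihood gradient is below `tol` (default $10^{-3}$;
Az values are unchanged against refits at $10^{-8}$, which the tests verify
against a brute-force refit oracle). This matters because the significance
threshold repeats the *entire* LOO procedure after randomizing the labels,
1000 times: the threshold is the empirical $1-\alpha$ quantile
($\alpha = 0.01$) of the pooled null Az values. Pooling across windows is
the default (a per-window threshold); a familywise variant (max across
windows per randomization) is available by flag, since the choice is not
dictated by anything in the analysis itself. `bootstrap_centers` may name a
subsampled window grid for the null (the pipeline uses every 100 ms, 9
windows) — the null Az distribution is essentially exchangeable across
windows under label randomization.

Components are strict local maxima of the Az curve above threshold, thinned
to a minimum separation of 100 ms (keeping the higher peak; ties break
earlier), at most two, labelled `early`/`late` in time order. Their
temporal profiles apply the peak-window spatial weights (no intercept — the
spatial pattern only) across the −200..600 ms window, averaged separately
by outcome.

## Numerical and degenerate-input choices

* Half-open epoch windows; closed window-average intervals (symmetric
  around the centre, so a linear ramp averages to its midpoint exactly).
* Zero-variance channels abort z-scoring with the channel named.
* Quantiles everywhere are type-7 (linear interpolation), the common
  statistics-package default.
* Rank-sum tests use the normal approximation with tie and continuity
  correction; Kruskal–Wallis applies the tie correction, and an all-equal
  input returns $H = 0$, $p = 1$ rather than an error.
* Trials with no predecessor are excluded from transition tables and
  counted (`n_excluded`). The published table's four counts sum to the
  total trial count, which no real sequence reproduces (796 trials have 795
  transitions); how first trials were counted there is unknowable from the
  printed numbers, so the package keeps them out and reports the exclusion.
* Every stochastic step takes an explicit integer seed, and identical
  seeds give bit-identical output, including the full pipeline report.

## Problem sizes used by the checks

The test suite and the acceptance script run at fixed, deliberately chosen
sizes: calibration of the bootstrap threshold uses 20 replicates × 200
trials × 8 channels × 1000 label randomizations on a 9-window grid;
latency recovery uses 20 runs of ~190 trials with 7 µV injections
(window-averaged effect size $d \approx 1.5$, measured) against a
200-randomization threshold; ERSP null calibration uses 20 runs of 40
trials with 200 permutations; the lateralization checks pool three
simulated sessions (~230 trials) with 500 permutations. These sizes give
the binomial error bars quoted in the tests while keeping a full run in the
minutes range on one core.

## What passing tests do and do not show

The generator emulates the *structure* the analyses assume: task schedule
and timing, 1/f background, line contamination, theta-band bursts whose
amplitude and latency depend on outcome, expectancy and hemisphere, RT
distributions with post-error slowing. It does not emulate non-stationary
artifacts, movement or electrode drift, volume conduction between
channels, cross-frequency coupling, or any within-session learning-related
drift of the LFP response. Passing the injection-recovery and
lateralization tests therefore shows the pipeline recovers effects of the
assumed form at generous signal-to-noise ratios — it is a correctness
check of the analysis code, not evidence about real dACC physiology, and
subject-level empirical magnitudes (ERP peak sizes, empirical Az curves)
are inherently not reproducible without the recordings.

## Known limitations

* The agent model has no perseveration and underestimates repeated-error
  runs (see above).
* Pixelwise FDR on permutation p-values is conservative at practical
  permutation counts; cluster-based correction is out of scope.
* The EDF writer/reader covers plain EDF with a uniform channel rate and
  one-second records — enough for interchange, not a general EDF+ suite.
* Univariate vs multivariate comparisons share the ridge penalty; no
  per-channel tuning is attempted.
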