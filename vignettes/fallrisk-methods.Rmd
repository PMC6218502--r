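---
title: "Methods: sensor-based fall-risk measures, screening and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor-based fall-risk measures, screening and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallrisk)
```

## The problem and the pipeline

Retrospective fallers (two or more falls, or one injurious fall requiring
medical attention, within the past year) are to be distinguished from
non-fallers using inertial recordings from a seven-subtest battery.  The
pipeline is: filter the raw channels, extract a fixed catalogue of 155
scalar measures per subject, screen the measures univariately (two-sample
t-test and ROC analysis), rank the survivors by random-forest permutation
importance, and classify fallers with six cross-validated models.  Because
the clinical cohort is not publicly available, every stage is exercised on
synthetic data whose ground truth is known by construction; the published
group means and SDs (n = 114 non-fallers, 82 fallers) parameterize the
feature-level simulator.

## Signal processing

**Filtering.** All channels pass through a zero-phase fourth-order low-pass
Butterworth with a 20 Hz cutoff.  Zero phase matters because event *times*
are the payload; a causal filter would delay every detected gait event by
the group delay.  We realize the filter in the frequency domain: the series
is odd-reflection padded (default one second) and multiplied by the exact
two-pass magnitude $|H(f)|^2 = 1/(1+(f/f_c)^{2\cdot 4})$.  A
bilinear-transform IIR applied forward–backward would have the same
passband but a warped stopband — at 40 Hz with a 100 Hz rate it attenuates
to $\sim 10^{-5}$ rather than the analytic $1/257 \approx 0.0039$.  The
frequency-domain form realizes the analytic law at every frequency, which
is what the package's oracle tests pin down.  Consequence to note: the
"order 4" filter has the *squared* single-pass response, as any filtfilt
application would.

**Derivatives (jerk).**  Second-order central differences, one-sided at the
edges; a linear ramp maps to its exact slope.  The scheme's gain is
$\mathrm{sinc}(2\pi f/\mathrm{rate})$: at $f = \mathrm{rate}/20$ the
derivative RMS of a sinusoid is 1.64% low.  This is inherent to the
standard formula, not an implementation artifact; tests assert 1% up to
3 Hz and 2% at 4–5 Hz (100 Hz rate).

**Tilt.**  When orientation (Euler) channels exist they are used directly
(pitch → anteroposterior, roll → mediolateral).  Otherwise the gravity
direction is isolated by a 0.5 Hz low-pass on acceleration
(`tilt.gravity_cutoff_hz`) and tilt is the inclination
$\theta_{AP} = \operatorname{atan2}(a_x, a_z)$.  The 0.5 Hz default trades
sway-band leakage against gravity-tracking lag; it only affects the
acceleration route.

## Feature extraction

The measure set is *data*: `measure_catalogue()` is a declarative table
(155 rows: id, subtest, sensor, direction, statistic, units, domain) and
`extract_all()` computes whatever the table lists, flagging anything the
supplied sessions cannot support as missing rather than failing.  Counts:
4 SIT conditions × 26 + 6 sensory ratios + 7 LOS + 12 STS5 + 21 TUG +
2 MF + 2 CRT + 1 FES = 155.

**Sway scores.** RMS follows the sway convention (mean-removed).  The
equilibrium score is $100\,(1 - \text{range}(\theta)/\theta_{\max})$
clamped to $[0,100]$ with $\theta_{\max} = 12.5^\circ$, the conventional
sagittal limit of stability in posturography (configurable).  The three
sensory systems are scored as ratios against the eyes-open/firm reference
condition (somatosensory = EC-firm, visual = EO-foam, vestibular =
EC-foam, each ×100, capped at 100); raw per-condition scores are also in
the catalogue because the ratio construction is a convention, not a law.

**Gait events.**  On the filtered shank sagittal angular velocity,
mid-swings are local maxima above an adaptive threshold
$\max(0.4\cdot\max|\omega_y|,\,50\ \text{deg/s})$, with a minimum peak
separation of 0.4 × the median inter-peak interval (a rough first pass
estimates that median).  Toe-off and heel-strike are the deepest troughs
in the half-cycle windows before and after each mid-swing; "deepest in
window" rather than "nearest local minimum" because sensor noise creates
spurious dimples adjacent to the peak.

**Turn.**  Mid-swings from both legs are merged; an inter-swing gap
exceeding 1.8 × the median marks the turn.  Turn start is the last
mid-swing before the gap; turn end is the first post-gap mid-swing whose
amplitude is below the contralateral leg's next peak (the cautious pivot
step).  Turning time is their difference, and the low-back yaw rate inside
the window yields RMS/mean/max turn angular velocity (computed on the raw,
not mean-removed, signal — the turn is a one-sided pulse).

**Step definitions.**  The printed definition of step time (interval
between consecutive *same-foot* toe-offs) is conventionally a stride time,
and it is internally inconsistent with counting steps across both feet for
step length.  Both are emitted: `tug_step_time` (same-foot, the printed
definition) and `tug_step_time_alt` (alternating-foot).  Walking time is
last heel-strike minus first toe-off minus turning time; gait velocity is
total distance (2 × walkway, default 3 m — the walkway length is never
stated and is configurable) over walking time.

**STS5.**  The rectified, filtered thigh angular velocity is thresholded
at 10% of its maximum to find five active regions (gaps under 0.25 s are
bridged — the zero crossing between the sit→stand and stand→sit lobes dips
below any threshold).  Boundaries are then *refined per cycle*: the
crossing of 10% of that cycle's own lobe peak, linearly interpolated
between samples.  Without sub-sample interpolation the grid quantization
alone costs up to two samples per duration, which would violate the
package's own ±1-sample recovery target.  Exactly five cycles are
required; anything else is a cycle-count error.

**Knee ROM.**  Knee angle is lower-leg minus upper-leg sagittal
orientation; without orientation channels each segment angle is the
integral of the sagittal gyro with a linear detrend over the trial (first-
order drift correction).  ROM is max − min.

**CRT / FES.**  Information processing speed is
$\log_2(\text{alternatives})$ over the mean correct choice reaction time
(bits/s), averaged over choice blocks; simple reaction time is the mean
over correct single-alternative trials.  FES is the 7-item (1–4) sum; the
published group means (9.73/14.96) fit this short form's 7–28 range.

## Screening

Pooled (Student) two-sample t-tests are used rather than Welch: pooled
reproduces the published demographic p-values (0.006 for weight, 0.001 for
BMI, at printed precision) where Welch does not.  ROC discrimination is
the empirical AUC (tie-aware, orientation recorded so AUC ≥ 0.5) with the
Hanley–McNeil standard error; a measure is "discriminative" when the 95%
CI excludes 0.5 — the publication never states its ROC criterion, and this
CI rule is the natural reading.  A measure is *selected* when significant
on both.  No multiple-testing correction by default (matching the raw
p < 0.05 screen); Benjamini–Hochberg is available via `adjust = "BH"`.
Importance ranking is classic permutation importance: per tree, the drop
in out-of-bag accuracy when one feature is permuted among that tree's OOB
rows, averaged over 500 trees, ties broken by AUC then p.

The identity of the 38 measures the original screen retained is in an
unavailable supplement; `screened_reference()` is a clearly-labelled
synthetic reconstruction (the measures the results narrative names, padded
with same-family neighbours to 38) used as the demo predictor set only.

## Classification

Six models with faller as the positive class; standardization and mean
imputation are fitted on the training folds only.  Published
configurations are unstated, so defaults are explicit substitutes:

| model | defaults |
|---|---|
| logistic regression | plain `glm.fit`, no penalty |
| naive Bayes | Gaussian, per-class feature normals, SD floor 1e-6 |
| decision tree | CART; cost-complexity cp chosen by internal 5-fold CV with a one-SE rule |
| boosted tree | gradient boosting, logistic loss, 100 stages, depth 3, learning rate 0.1, Newton leaf steps |
| random forest | 500 trees, mtry = ⌊√d⌋, leaf size 5 |
| SVM | RBF kernel, C = 1, γ = 1/d on standardized features; exact dual QP via `quadprog` |

The one-SE pruning rule matters: with a fixed cp the tree fits noise on
label-free data; with CV pruning a null tree collapses to the
majority-class root, which is the behaviour the no-leakage checks expect.
Folds are stratified (class proportions within one subject per fold, total
sizes balanced) and the default scheme is 10 × 10-fold so model-comparison
t-tests have a distribution.  `compare_models()` runs pooled t-tests on
per-fold accuracies with a 95% CI on the mean difference.

## What the synthetic generators emulate — and what they do not

`simulate_tug` writes shank angular velocity as Gaussian swing lobes
(σ = 5% of stride — any smooth unimodal lobe works; Gaussians make event
timing analytic) with negative toe-off/heel-strike lobes at ±25% of the
stride, legs alternating, a swing-free turn window whose boundary swings
sit exactly on the window edges, a flat-top low-back yaw pulse, and white
gyro noise.  `simulate_sway` writes band-limited Gaussian processes
(default 1 Hz, within the sub-1 Hz physiological sway band) rescaled so
the realized mean-removed RMS equals the target *exactly*, plus consistent
gravity-decomposition orientation channels.  The generated noise is
pre-passed through the pipeline's 20 Hz filter so extraction is a near
no-op; the residual in-band gain deficit still leaves ≈2 × 10⁻⁹ absolute
RMS error on a 0.02 m/s² signal, which is why the round-trip tests assert
5 × 10⁻⁹ rather than 10⁻⁹.  `simulate_sts5` shapes lobe ramps so the
10%-of-peak crossings land on the scheduled boundaries.  Cohort-level
parameters (stride and turn times, transition durations, ROM, IPS, FES)
are drawn from the published group normals; measures whose group means
were not printed received one-time plausible values with the reported
effect direction (`source == "synthetic"` in `default_measure_stats()`).

Not emulated: soft-tissue artifact, magnetometer content, gait asymmetry
pathologies, turn strategies other than a clean gap, within-subject
correlation among the 155 measures (independent normals by default; a
correlation matrix is accepted for robustness studies, and no test depends
on it).  A green test therefore establishes algorithmic correctness
against the stated waveform model — not clinical validity on real
recordings, and not the published cohort's headline accuracies (89.4%
SVM), which are out of reach without the cohort.

## Numerical choices and degenerate inputs

Uniform-sampling tolerance is 1 µs on successive deltas; files with
dropped samples raise a sampling error listing gap indices (no silent
resampling).  Round trips through the session CSV are lossless to 1e-9
relative (values printed at 15 significant digits).  Degenerate t-tests
(zero pooled variance) return p = 1 at equal means by convention.  AUC
with a single class is an error; all-tied scores give 0.5.  Zero-RMS sway
requests produce exactly constant signals.  Reproducibility: every
stochastic routine takes a seed; cohort subjects use per-subject seed
substreams (`master*1009 + i*7907 mod 2³¹−1`) so truncating a cohort never
changes the subjects that remain; the C++ tree code uses its own xorshift
RNG, leaving R's RNG state untouched.

## Known limitations

* **Permuted-label baseline (one deliberately red check).**  The package's
  acceptance suite asserts that permuting labels drives *every* model's CV
  accuracy to the majority rate (58.2% at 114/82) ± 3 points.  That is a
  theorem only for models that revert to priors.  Flexible learners fit
  noise in the training folds, so their held-out predictions are partly
  independent of the majority class and their expected accuracy falls
  *between* 50% and 58.2% (measured here: boosting ≈ 49–54%, random forest
  ≈ 52–55%, RBF-SVM ≈ 53–55%; reference implementations behave the same).
  The check is implemented faithfully and left red for those three models
  rather than widened; the collapse it is really after — no residual skill
  after permutation — does hold for all six.
* Sensor-to-segment alignment is assumed perfect (axis conventions are
  taken at face value from the file).
* The turn detector assumes one turn; multi-turn protocols would need the
  gap rule generalized.
* The LOS reach estimate (height × sin peak pitch) is a small-angle trunk
  model, flagged as an estimate in the output.
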