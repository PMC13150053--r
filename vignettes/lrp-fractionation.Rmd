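---
title: "Fractionating choice reaction time with the lateralized readiness potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractionating choice reaction time with the lateralized readiness potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrpfrac)
```

## The problem

Choice reaction time (RT) is a composite: the interval from stimulus
onset to the overt response contains stimulus evaluation and response
selection (premotor processing) followed by motor programming and
execution. Questions about *which* of these stages drives individual or
developmental differences in processing speed cannot be answered from RT
alone. The lateralized readiness potential (LRP) — a difference waveform
isolating hand-specific motor-cortex activation — provides a split
point: the latency from stimulus onset to LRP onset (S-LRP latency)
indexes premotor duration, and the latency from LRP onset to the
button press (R-LRP latency, reported as a positive duration) indexes
motor duration.

`lrpfrac` implements this fractionation end to end for a two-choice
flanker task, together with the inferential chain that typically follows
it in developmental work: per-subject latency scoring, behavioral
cleaning, cohort correlations, a commonality decomposition of RT
variance, a dual-mediator path model of age effects on RT, and Monte
Carlo power for the mediation paths. Because raw developmental EEG
cohorts are rarely shareable, the package also contains a first-class
synthetic cohort generator with known ground truth, so that every stage
is testable and the whole pipeline can be exercised without any
download.

## The generative model

`cohort_config()` fixes the study conditions. Age is uniform on 14–19
years and standardized, matching a continuous-age adolescent design
(this regime reproduces an age SD near 1.7 years). Sex is
Bernoulli(0.686 female) and influences RT only. Each subject carries two
latent durations, a premotor mean and a motor mean, generated from the
same standardized path structure the analysis later estimates:

- `a_S` (default −0.22): standardized effect of age on the premotor
  mean;
- `a_R` (default 0.087): standardized effect of age on the motor mean;
- `rho_med` (default −0.12): correlation of the two mediator
  disturbances;
- `beta_sex` (default 0.221): standardized effect of sex on RT.

Premotor and motor means sit on ms scales (defaults 191 ± 40 ms and
152 ± 36 ms) chosen to match the descriptive regime of adolescent
flanker data. Per-trial durations scatter around the subject means:
the premotor component receives ex-Gaussian noise (Gaussian SD
`sigma` = 35 ms plus a centered exponential with mean `tau` = 45 ms),
the motor component Gaussian noise with SD `sigma/2`. The right-skewed
share is assigned to the premotor stage so that the EEG onset implied by
the premotor duration stays consistent with the behavioral RT; on every
correct trial `rt_ms` equals `premotor_ms + motor_ms` exactly, by
construction rather than by accident. Flanker interference lengthens
the premotor stage by half of `compat_effect_ms` (default 36.5 ms, so
the compatible-minus-incompatible RT effect is −36.5 ms). No published
per-trial variability estimates exist for this design, so the noise
magnitudes are free parameters of the generator, fixed once; they are
not estimates of any particular dataset.

Rendered EEG inverts the LRP definition. On each trial a piecewise-
linear lateralized ramp begins `premotor_ms` after the stimulus marker,
peaks at the response marker, and decays over 300 ms; the per-channel
deflection is a quarter of `lrp_amplitude` with opposite signs over C3
and C4, so the derived double-subtraction LRP has amplitude
`lrp_amplitude` (default 3 µV). The ramp is deliberately inside the
model class of the segmented-regression onset estimator: noise-free
recovery is then exact to one sample, and noisy cases test robustness
rather than model mismatch. A hand-independent stimulus-evoked bump is
added identically to C3 and C4 (it must cancel in the double
subtraction), mastoids carry reference noise, and VEOG/HEOG carry
raised-cosine blink templates that propagate to the scalp with fixed
factors (0.15 and ±0.08), giving the ocular-correction stage something
real to estimate. Background noise is band-limited (low-passed at
30 Hz) Gaussian noise, default SD 8 µV per channel. Stimulus onset
asynchrony is the 250 ms stimulus duration plus an inter-trial interval
drawn from {1080, 1100, 1130} ms. The generator does not attempt
volume-conduction head modeling, 1/f spectra, or oculomotor physics;
consequences for interpretation are discussed at the end.

## Preprocessing

`preprocess_and_score()` runs the reduction chain in a fixed order:
average-mastoid re-referencing; a second-order Butterworth band-pass
(0.1–30 Hz) applied forward–backward (zero phase, which doubles the
effective order — the conventional reading of "second-order,
zero-phase" in commercial ERP software); a biquad 60 Hz notch with
quality factor 30, narrow enough to spare the 30 Hz band edge;
segmentation of correct trials only (stimulus-locked −200–600 ms with
−200–0 baseline; response-locked −1000–200 ms with −1000 to −800
baseline, placed before stimulus onset to avoid contamination from
stimulus processing); regression-based ocular correction; baseline
correction; and four-rule artifact rejection. Baseline correction runs
after ocular correction because the correction changes offsets.

Two numerical conventions are stated explicitly because they are easy
to get subtly wrong: milliseconds convert to samples by rounding half
away from zero (base R's banker's rounding would make the conversion
parity-dependent), and epoch windows are half-open `[start, end)`, so
the 800 ms stimulus-locked window is exactly 400 samples at 500 Hz.

Ocular correction follows the classic regression approach: the
per-condition event-related average is subtracted from every trial (EEG
and EOG alike), propagation factors are estimated by least squares of
residual EEG on residual VEOG and HEOG pooled over trials and samples,
and `factor × raw EOG` is then subtracted from the raw EEG. The
average-subtraction step exists to keep event-locked activity out of
the factors; a test demonstrates that omitting it biases the estimated
factor when the EOG carries an event-locked component. Correction is
applied to segments (not the continuous record), consistent with
pipelines that describe correcting "all segments".

Artifact rejection flags a trial when any scanned channel (default: all
except the EOG pair; configurable, since published pipelines rarely say)
violates any of: absolute voltage above 100 µV; peak-to-peak range above
175 µV in a moving 100 ms window; an adjacent-sample step above
30 µV/ms (60 µV per sample at 500 Hz — the unit conversion matters: a
31 µV step at 500 Hz is only 15.5 µV/ms and must *not* fire); or a
moving-window range below 0.5 µV (dead channel). Windows advance one
sample at a time. One consequence worth knowing: a strictly noise-free
synthetic recording has flat baselines and is therefore *rejected* by
the low-activity rule — that rule presumes physiological background
activity. Noise-free recovery demonstrations therefore disable
rejection, and "clean data" tests use low-amplitude background noise.

## LRP derivation and onset scoring

`derive_lrp()` computes mean(C3 − C4 | left hand) − mean(C3 − C4 |
right hand) over retained correct trials. With this subtraction order,
contralateral motor negativity yields a positive-going LRP, so peaks
are maxima; the opposite averaging convention is also common in the
literature, which is why the polarity is stated rather than assumed.
Two exact identities follow from the algebra and are tested as such:
activity common to both channels or both hands cancels, and swapping
hand labels negates the waveform.

Peaks are detected as window maxima (stimulus-locked: 200–500 ms;
response-locked: −200–100 ms), ties resolved to the earliest sample.
`estimate_onset()` then fits, for every candidate breakpoint τ on the
sample grid between the search-interval start and the peak, the
continuous two-segment model

y(t) = c for t ≤ τ, and y(t) = c + s·(t − τ) for t > τ,

by least squares, returning the τ with minimal residual sum of squares
(earliest on ties). The pre-onset slope is fixed at zero and the two
segments share the level c — the one-structural-parameter reading of a
"two regression lines intersecting at the onset". The search is an
exhaustive scan at one-sample granularity with no subsample
interpolation; a test asserts exact agreement with an independent
brute-force implementation on every tried input. The onset search
begins at the baseline start (−200 ms stimulus-locked, −1000 ms
response-locked); this choice is configurable because the alternative
(starting at the lock event) is equally defensible.

S-LRP latency is the stimulus-locked onset; R-LRP latency is the
negated response-locked onset, reported as a positive duration before
the button press.

Two estimator properties deserve emphasis. First, on noise-free data
whose waveform is in the model class, recovery is within one sample
end to end — through rendering, filtering, segmentation, and scoring.
Second, averaging over trials with variable onsets smears the average
waveform leftward: the average of ramps beginning at different times
departs from baseline near the *earliest* trial onset. Single-subject
onset estimates on jittered data are therefore biased early relative to
the mean latent premotor duration. This is a property of all
average-waveform onset measures, not of this estimator; recovery tests
that target the estimator itself use low-jitter regimes, and
cohort-level analyses rely on between-subject ordering (which survives
smearing) rather than absolute calibration.

## Behavioral cleaning

`clean_rts()` removes, per subject and in order: error trials; RTs
below 100 ms; and RTs at or above the subject mean plus 3 SD, where
mean and SD are computed once on the trials surviving the first two
steps (a single pass — iterating the fence would be a different,
stricter estimator). The fence is upper-tail only, as is conventional
when a hard response deadline (1000 ms) already bounds the slow tail.
When the surviving RTs have zero spread the fence is vacuous and
removes nothing — removing every identical trial would be absurd.
Accuracy is counted against all administered trials, since chance
performance is defined on the full task. `binomial_chance_threshold()`
computes the exact binomial tail: for 300 trials at α = 0.01 the
minimal above-chance accuracy is 171/300 = 57%. The threshold value
itself passes; exclusion is strictly below it.

`winsorize()` operates at the cohort level: values at or beyond 3 SD
from the sample mean (single pass, two-sided) are replaced by the most
extreme value on the same side that is not outlying.

## Cohort inference

`pearson_matrix()` reports r with two-sided p from
t = r√((n−2)/(1−r²)). `compare_dependent_correlations()` implements the
Meng–Rosenthal–Rubin z for two overlapping dependent correlations as
the default, with the independent-samples Fisher z as an option; the
overlapping variant is the appropriate one when both correlations share
a variable measured on the same sample, but both are provided because
published reports frequently do not say which was used (and printed z
values in this literature often match neither formula applied to the
rounded printed correlations — a reason to treat such values as
descriptive, not as reproduction targets).

`commonality_two_predictor()` decomposes the R² of a two-predictor
regression into the variance unique to each predictor and their common
(shared) variance via the three hierarchical regressions. The common
component may legitimately be negative — a suppression signature typical
when predictors share little variance — and the three components sum to
the total R² as an algebraic identity, which the tests verify to 1e−10.
The decomposition is computed from regressions rather than correlation
shortcuts so covariates could be added later; the two-predictor case is
the supported scope.

`fit_trial_lme()` fits the trial-level mixed model (RT or trial
correctness on standardized age × compatibility (+0.5/−0.5) × centered
sex, with by-subject random intercepts and compatibility slopes) via
`lmerTest`. The accuracy model is a linear probability model, not a
logistic one, mirroring how such models are typically reported for
proportions in this literature.

## The dual-mediator path model

`fit_path_model()` estimates the recursive system

- S = a_S·age + e_S, R = a_R·age + e_R, cov(e_S, e_R) = ψ,
- RT = c′·age + b_S·S + b_R·R + β_sex·sex + e_RT.

For a recursive path model with uncorrelated equation errors across
blocks, the maximum-likelihood point estimates coincide with the
two-stage OLS estimates, so the package computes them in closed form —
fully auditable, no optimizer, no convergence nondeterminism. A test
verifies this equivalence independently by numerically minimizing the
ML covariance discrepancy and recovering the same estimates. The
standardized solution z-scores all five variables (the `standardize =
FALSE` path mean-centers the mediators and RT, keeping ms units).

Indirect effects are a·b products with delta-method standard errors
√(a²SE_b² + b²SE_a²); the total effect is c′ + a_S·b_S + a_R·b_R,
an exact identity on every fit. Model fit is evaluated from the
implied covariance of the five observed variables; the only
over-identifying restrictions are the omitted sex→mediator paths, so
df = 2. χ² = (n−1)·F_ML; RMSEA is defined as 0 at df = 0; SRMR averages
squared standardized residual moments; CFI/TLI use the independence
baseline.

`monte_carlo_power()` draws replicate cohorts from the multivariate
normal distribution implied by a standardized parameterization, refits
the model per replicate, and counts significant delta-method indirect
effects. The implied covariance construction solves for the RT
disturbance variance that makes all variances unity and refuses
non-positive-definite parameterizations. Replicates are re-standardized
before fitting, matching the standardized fitting procedure. Under a
complete null the product test is conservative (its rejection rate
falls below α rather than at it) — a well-known property of
delta-method product tests, and the reason the null-calibration test
asserts an upper bound. The sex covariate participates in the
generating model by default but can be toggled, since power reports in
the literature rarely state whether covariates entered the simulation.

## Problem sizes and numerical choices

The test suite and examples run at deliberately modest scales: cohorts
of 10–20 subjects with 60–120 trials for end-to-end EEG runs (a
20-subject, 100-trial pipeline completes in a few minutes on one CPU),
2000–5000 subjects for generative-recovery checks, 10⁵ rows for
large-sample consistency of the path model, and 400–5000 replicates for
power calibration, with 5000 replicates in the headline power
computation. Ties in peak detection and onset search resolve to the
earliest sample; all-constant waveforms return a flagged (degenerate)
onset rather than an arbitrary number; zero-variance EOG channels get
zero propagation factors with a warning; subjects falling below 20
retained correct trials per hand (configurable) are marked unusable
rather than scored.

## What passing tests do and do not show

The synthetic cohort has, by construction, the statistical structure
the analysis assumes: linear age effects, Gaussian mediator
disturbances, an LRP waveform inside the onset estimator's model class,
stationary band-limited noise, and artifact exemplars that match the
rejection rules. Passing tests therefore demonstrate that the
implementation is faithful — estimators recover known ground truth under
the stated conditions — not that real adolescent EEG satisfies those
conditions. Real data bring non-piecewise-linear LRP shapes, 1/f and
alpha-band noise, ocular artifacts that are not pure templates, and
latency jitter whose smearing bias (discussed above) applies to any
average-waveform onset measure. The package's value on real data is
that every rule it applies is explicit, tested, and configurable.

```{r example, eval = FALSE}
cfg <- cohort_config(n_subjects = 20, n_trials = 100, seed = 1)
res <- run_pipeline(cfg, out_dir = "demo_out", power_reps = 1000)
res$path_model
res$power
```
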