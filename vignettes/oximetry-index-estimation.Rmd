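---
title: "Estimating AHI and ODI from the oximetry signal: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating AHI and ODI from the oximetry signal: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(oxinet)
```

## The problem

Obstructive sleep apnea (OSA) is diagnosed from the apnea–hypopnea index
(AHI, apneas plus hypopneas per hour of sleep) and screened with the oxygen
desaturation index (ODI, ≥4-point desaturations per hour). Determining these
indices normally requires multi-channel polygraphy and manual event scoring.
Because most obstructive events leave a signature in the oxygen saturation
trace — a transient desaturation followed by resaturation — a single-channel
pulse-oximetry recording carries enough information to estimate both indices
directly.

`oxinet` implements that estimator: a small feedforward network regresses
overlapping 10-minute SpO2 epochs onto per-epoch event rates; averaging the
epoch predictions over the night yields the full-night AHI or ODI, which is
then mapped to the standard severity classes (no OSA < 5, mild 5–15,
moderate 15–30, severe ≥ 30 events/hour; boundaries belong to the higher
class). Two networks with identical machinery but different regression
targets produce the AHI and ODI estimates independently.

Clinical oximetry corpora are not redistributable, so the package also ships
a synthetic cohort simulator with known ground truth. Every pipeline stage —
preprocessing, training, scoring, evaluation — runs end to end against
simulated cohorts, and all claims made by the test suite are claims about
recovery of *known synthetic* parameters, not about clinical accuracy.

## Preprocessing

A recording (nominally 4 Hz) is decimated to 0.5 Hz by block averaging —
each output sample is the mean of 8 input samples, which doubles as an
anti-alias filter and smooths the oximeter's integer quantization. The
downsampled trace is cut into 10-minute epochs (300 samples) with 98%
overlap, i.e. a 12 s stride, so a recording of `T` seconds yields
`floor((T − 600)/12) + 1` epochs; a trailing partial window is discarded
because the network input dimension is fixed at 300.

Per-epoch regression targets are `6 ×` the number of relevant event onsets
inside the window, putting targets in events/hour. Assignment is by event
*onset*: an event whose onset falls inside several overlapping windows
counts once in each. With this convention the epoch-target average over a
night approaches the night's reference index, so the epoch-mean aggregation
at prediction time is consistent with the target definition (edge effects
are O(window/duration)).

Invalid samples (artifacts) are carried as `NA` end to end. An epoch whose
invalid fraction exceeds 10% (configurable) is excluded; remaining gaps in
valid epochs are filled by linear interpolation only at the point where the
fixed-size numeric matrix is built.

## The network and its training

The regression model is a 300–60–15–5–1 fully connected network. The three
hidden layers use the symmetric sigmoid `2/(1 + exp(−2z)) − 1` (identically
`tanh`); the output is linear, the usual regression convention — a sigmoid
output is available as a configuration switch but is not the default, since
a bounded output would have to be stretched over a 0–150 events/hour target
range. Inputs and targets are min–max normalized to `[−1, 1]` using
training-set statistics only; constant features map to 0. Negative
predictions are clamped to zero — an event rate cannot be negative.

Training minimizes mean squared error (in normalized target space) with
Møller's scaled conjugate gradient (SCG), full batch: conjugate search
directions, curvature along the direction estimated by a finite difference
of the gradient (scale `sigma = 5e-5`), and a Levenberg-style parameter
`lambda` (initial `5e-7`) that is raised when the local quadratic model
fails and lowered when it fits well. Both constants are Møller's recommended
values and configurable. Weights start from a scaled-uniform draw on
`±sqrt(6/(fan_in + fan_out))`, biases at zero, reproducibly from a seed.

After every iteration the validation MSE is evaluated. When it has failed to
improve on its running best for 100 consecutive iterations (configurable),
training stops and the parameters from the best-validation iteration are
returned — so the returned model is exactly the iterate with minimal
validation error seen, not the last one. A hard iteration cap bounds total
compute; the default cap is 800 iterations, chosen so that a full default
experiment trains both networks in a few minutes on one CPU core.

Gradient correctness is the load-bearing property of the whole module and
is tested directly: reverse-mode gradients must match central finite
differences to a relative error below `1e-6` across randomized
architectures, and SCG must reproduce the closed-form least-squares solution
when the network is linear.

## The desaturation detector

The AASM-style rule ("a drop of at least 4 percentage points", absolute, not
relative) is operationalized as a sliding-baseline state machine: the
baseline at time `t` is the maximum valid saturation over the preceding
120 s; a candidate opens when the signal falls ≥ 4 points below baseline,
its nadir is the minimum before recovery, and it closes on return to within
1 point of the opening baseline or after 300 s. The reported onset is
backtracked from the threshold crossing to the last near-baseline sample, so
that onsets align with the shoulder where the decline began. Invalid samples
terminate candidates; overlapping candidate spans are merged. The window,
margin and timeout are calibration knobs, not claims: manual scorers'
baseline conventions vary, and the defaults were chosen once as reasonable
HSAT practice. The detector is verified against a brute-force oracle — a
naive per-sample transliteration of the same definition with exhaustive
window scans — on 1000 random traces per run.

The index denominator is total valid recording time (the home-sleep-apnea-
test convention); without EEG there is no sleep staging, so true
sleep-time-based indices are out of reach and estimates are conservative.

## The simulator: what it emulates, and what it does not

Each synthetic patient is a profile: target AHI, apnea fraction,
desaturation yield, baseline saturation, desaturation depth distribution,
event and resaturation durations, oximeter noise and artifact rate. Cohort
defaults emulate a suspected-OSA referral population: severity shares
48.6 / 25.4 / 12.9 / 13.1% (no OSA / mild / moderate / severe), AHI spanning
0–150 events/hour with a long-tailed severe class (30 + Exp(25), capped),
apnea fraction Beta(1.5, 7) (median ≈ 0.16), desaturation yield
Beta(18, 1.5) (mean ≈ 0.92, so cohort ODI sits just below cohort AHI),
baseline SpO2 ~ Normal(96.5, 1) truncated to [92, 99], depth mean per
patient Uniform(5, 9) points, noise 0.2–0.8 points, artifacts 0–1
dropouts/hour.

Events are planted by a homogeneous Poisson process with hard-core
non-overlap (sorted uniforms on the free interval after reserving event
lengths plus a 2 s guard), the simplest process with a controllable rate. At
high rates the inter-event cycle bounds event duration, so profile durations
are drawn below `0.6 × 3600 / AHI`; a profile whose load cannot fit is
rejected with the rate named. Each event desaturates with probability
`desat_yield`; depths are normal, truncated to ≥ 4 points for desaturating
events and < 4 otherwise (sub-threshold dips still perturb the trace, as in
real recordings). Desaturation onset lags the respiratory event by a fixed
15 s circulation delay. The waveform falls linearly at a bounded rate (fall
time ≤ 15 s, matching typical desaturation slopes of a few tenths of a
point per second), holds the nadir while the obstruction persists, and
recovers exponentially (τ = resaturation/4, ≈ 98% recovered at the nominal
20 s resaturation). Overlapping dips combine by pointwise maximum deficit,
so an unfinished recovery is truncated when the next event begins — the
oscillating morphology of severe OSA. Gaussian noise is added, the trace is
rounded to integer percent (oximeters report whole-percent values), and
artifact dropouts become `NA` runs.

What the simulator does **not** model: sleep stages and REM/NREM-dependent
event rates, central apneas, body position, flow-limitation morphology,
baseline drift, Cheyne–Stokes patterns, or oximeter-specific averaging
windows. Passing the end-to-end tests therefore demonstrates that the
pipeline recovers the generative parameters of this event-driven model of
oximetry — a necessary sanity property — and says nothing quantitative about
clinical recordings.

Above roughly 60 events/hour, successive desaturations overlap faster than
the resaturation time and distinct-event recovery becomes physically
ill-defined; per-event detector agreement is therefore asserted on clean
cohorts up to that rate, while index *regression* is exercised over the full
0–150 range (the network never depends on resolving individual events).

## The evaluation battery

For each test patient the reference index comes from the planted
annotation; the estimate is the epoch-prediction mean. The report contains
mean/median/min/max absolute error; median percentage error over patients
with non-zero reference (undefined at zero — those patients stay in the
absolute-error statistics); the 4×4 severity confusion matrix (reference in
rows, estimate in columns, serialized with labels); classification accuracy
(correct / total); the same error statistics restricted to misclassified
patients; and the intraclass correlation.

The ICC form is ICC(2,1): two-way random effects, absolute agreement,
single rater — chosen because the scientific question is agreement between
two raters (manual scorer vs network) measuring the same subjects, and
absolute agreement (not mere consistency) is what a diagnostic replacement
requires. The 95% CI uses the standard F-bounds with Satterthwaite degrees
of freedom. The implementation is closed-form from the ANOVA mean squares
and is tested against an independent `aov()`-based computation and an
external reference value on a fixture.

## Problem sizes and the default experiment

The default `experiment_config()` is a desk-scale analogue of a clinical
study: 600 training, 50 validation and 100 test patients, two-hour nights,
the training pool thinned to every 12th overlapping window (neighbouring
12 s-strided windows are nearly redundant), giving roughly 28 000 training
epochs. The validation pool is thinned less aggressively (every 4th window):
early stopping compares validation MSE values between iterations, and a
larger validation pool keeps that comparison from tracking sampling noise. The test split follows the sorted-AHI every-k-th-patient strategy so
the test set covers the full severity range; validation patients are drawn
at random from the remainder. With the 800-iteration cap, a full experiment
(simulate, train both networks, evaluate 100 patients) runs in about ten
minutes on one CPU core; every stage is seeded and bit-reproducible.

On this synthetic cohort the pipeline is required (and tested) to reach a
median absolute error of at most 5 events/hour, severity accuracy of at
least 0.80 and ICC of at least 0.90 for both indices. These acceptance
bounds are recovery criteria for the simulator's generative parameters at
desk scale — deliberately looser than published clinical performance of
comparable estimators, which was measured on cohorts an order of magnitude
larger with full-length nights.

## Numerical choices and degenerate inputs

* Decimation requires an integer rate ratio; anything else errors with both
  rates named.
* Records shorter than one window, empty batches, empty cohorts, mismatched
  record/annotation lists, all-invalid records and negative indices are
  rejected with explicit messages rather than propagating nonsense.
* A constant input feature normalizes to 0; the degenerate zero-range
  target maps all predictions to that constant.
* Non-finite training or validation loss aborts with the iteration named.
* Severity boundaries are left-closed exactly: 5, 15 and 30 belong to the
  higher class.
* Medians use R's default midpoint-of-middle-two convention.
* Model serialization stores IEEE doubles base64-encoded, so save/load
  round trips are bit-exact and run-to-run reproducibility can be asserted
  on file bytes.

## Known limitations

* The simulator's realism gap (above) bounds what green tests mean.
* The detector's parameters are calibration knobs; on real traces with
  drifting baselines its agreement with human scorers is untested here.
  On high-noise traces the max-over-window baseline rides the noise ceiling
  and fixed-threshold crossings become false-positive-prone — one
  motivation for the trained regressor, which is not bound to a threshold.
* Hypopneas associated only with arousals (no desaturation) are invisible
  to an oximetry-only estimator; estimates are systematically conservative
  relative to EEG-based scoring.
* The 4%-rule default matches AASM 2007 scoring; `min_drop = 3` gives the
  2012 variant but the networks would need retargeted training data to
  match it.
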