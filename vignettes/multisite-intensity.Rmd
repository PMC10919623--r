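---
title: "Multi-site accelerometry: simulation, MET ground truth, counts baselines and sequence classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-site accelerometry: simulation, MET ground truth, counts baselines and sequence classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Accelerometer-based physical-activity measurement traditionally converts
raw acceleration into device-style "activity counts" and maps counts to
intensity classes (sedentary / light / moderate / vigorous) with cut-points
calibrated for one wear-site, usually the hip. Two things go wrong in
practice: the cut-points are wear-site-specific, so a device worn at the
wrist or on a chest lanyard but processed with a hip protocol produces
biased intensity estimates; and compliance improves when participants may
choose where to wear the device, which is exactly what wear-site-specific
processing forbids.

`wearsite` implements the full measurement pipeline around this problem:

1. a **synthetic-data generator** for multi-site (hip / wrist / chest)
   100 Hz triaxial recordings plus indirect-calorimetry VO~2~ series for
   adult and child cohorts;
2. a **ground-truth stage** deriving resting VO~2~, steady-state bout
   VO~2~, metabolic equivalents (METs) and four-level intensity labels;
3. a **counts baseline** emulating ActiGraph-style counts and classical
   hip cut-points, including deliberate wear-site misspecification;
4. **windowing** of raw recordings into labeled 1-second windows;
5. **LSTM and stacked Bi-LSTM sequence classifiers** for wear-site
   detection and wear-site-agnostic intensity classification, optionally
   with anthropometric covariates;
6. **evaluation and report rendering**.

No laboratory dataset ships with the package; the generator is first-class,
tested code whose purpose is to make every downstream stage testable with
known ground truth.

# Ground-truth model

MET is defined as the ratio of a bout's oxygen consumption to resting
consumption, so the rest period is exactly 1 MET by construction
(`session_ground_truth()` hard-wires this identity), and every MET-derived
quantity is invariant to rescaling the whole calorimetry series. Intensity
classes use the standard cut-offs, half-open with boundaries belonging to
the upper class:

| METs              | class     |
|-------------------|-----------|
| < 1.5             | sedentary |
| 1.5 – < 3.0       | light     |
| 3.0 – < 6.0       | moderate  |
| ≥ 6.0             | vigorous  |

Resting VO~2~ is the mean over minutes 6–9 of a 10-minute seated rest.

## Steady-state detection

Practitioners average bout VO~2~ over a visually "trend-free" steady
segment of at least 3 minutes. We operationalize this with a quantitative
rule: scan all suffix windows of the bout (every window ending at the bout
end), and accept the longest suffix of duration at least
`steady_min_duration` (180 s) whose least-squares slope magnitude is at
most `trend_slope_tol`. Two numerical choices matter and both are
config-exposed:

* **Slope tolerance, default 0.3 (ml/kg/min)/min.** VO~2~ on-kinetics are
  first-order with a time constant near 30 s. A lax tolerance (e.g.
  1 (ml/kg/min)/min) silently admits the onset ramp, because a long flat
  tail dilutes the least-squares slope of a suffix that still contains the
  ramp; for a moderate bout this biases the recovered MET several percent
  low. 0.3 rejects suffixes containing meaningful onset transient while
  staying well above the slope noise floor of a 3-minute window at the
  generator's 3% bin noise (≈ 0.1 (ml/kg/min)/min, 1 SD).
* **Averaging window, `steady_avg_max_s` = 180 s.** The reported steady
  value is the mean over at most the final 180 s of the accepted suffix.
  Restricting the average to the late plateau makes the residual
  onset-lag bias negligible (< 0.5%), which the package verifies by
  comparing pipeline METs against the generator's stored latent draws.

Bouts with no qualifying window — including simulated steady-state
failures, where VO~2~ ramps for the entire bout — are excluded, and
excluded bouts contribute no windows downstream. One intensity label is
assigned per bout and inherited by all of its windows.

# The synthetic-data generator

The generator encodes exactly the three signals the classifiers need, and
no more:

* **Orientation → wear-site.** Each site has a distinct static gravity
  unit vector in device coordinates (hip ≈ y-down, wrist rotated toward
  x/z, chest tilted), plus slow orientation drift. This is what makes
  wear-site detection learnable, and the separation is asserted directly
  in tests.
* **Amplitude and gait frequency → intensity.** Each bout draws a latent
  MET level from a truncated normal with the configured per-group,
  per-category mean/SD (see below). Movement RMS grows linearly with
  (MET − 1) at `amp_per_met` = 0.22 g per MET, scaled by a site gain.
  Locomotor activities get a gait waveform — stride sway at half the step
  frequency, the step fundamental, one harmonic, and broadband impact
  noise — with step frequency increasing with MET and scaled by stature;
  non-locomotor activities get low-pass-filtered irregular movement.
  Chest recordings add a 0.25 Hz lanyard-sway oscillation; white sensor
  noise is added everywhere.
* **Anthropometric coupling → covariates.** The amplitude-to-MET mapping
  is modulated by (weight/60 kg)^−0.4^ · (age/25 y)^−0.2^, so lighter and
  younger participants move more per MET. Amplitude alone is therefore
  ambiguous across the adult/child pooled sample, and age/height/weight
  covariates carry real information — the mechanism behind the
  covariate-augmented models' advantage.

Per-bout latent MET draws and steady-state-failure flags are stored in the
session object, so parameter-recovery tests compare pipeline output
against the generator's own latents rather than against re-derived
quantities (non-circular by construction).

## Cohort statistics

Cohort defaults are the study-style distributions: adults 26.9 ± 8.7 y
with BMI 21.8 ± 2.0 kg/m²; children 12.1 ± 2.3 y with BMI
18.3 ± 2.5 kg/m²; resting VO~2~ 4.09 ± 0.98 (adult) and 5.71 ± 1.91
(child) ml/kg/min; per-category MET distributions (mean ± SD):

| category | adult | child |
|----------|-----------|-----------|
| sedentary-living / light | 1.7 ± 0.9 | 1.8 ± 1.0 |
| moderate | 5.8 ± 1.9 | 4.8 ± 1.5 |
| vigorous | 8.2 ± 2.3 | 7.7 ± 2.1 |

Only one aggregate "living or light" row is available for categories 1
and 2, so both categories share it. Adult ages are drawn from a shifted
gamma (18 + Gamma with mean 8.9, SD 8.7): a normal truncated at 18 would
inflate the realized mean by ≈ 2.4 y, whereas the shifted gamma keeps the
mean and SD exact under the adults-only constraint and gives the
right-skewed shape typical of volunteer samples. Heights are normal for
adults and an age-linear growth model for children; weight is derived
from BMI and height.

Protocols follow the laboratory design: a 600-s seated rest, then seven
bouts drawn without replacement from a 17-activity catalog — three from
category 1, three from categories 2–3, one from category 4 — each 300 to
480 s with 180-s rest gaps. Calorimetry is emitted in 5-s bins
(breath-by-breath structure is not modeled; only steady-state averages are
consumed downstream) with first-order on/off kinetics (τ = 30 s), 3%
multiplicative bin noise, and a 5% default rate of steady-state failures
simulated as a ramp that never settles.

## Count-emulation calibration

`amp_per_met` and the hip movement loading were fixed analytically — once,
ahead of any experiment — so that hip vertical-axis emulated counts line
up approximately with the classical counts-per-minute ↔ MET relationship
used by hip cut-point protocols (≈ 1952 cpm near 3 METs, ≈ 5725 cpm near
6 METs). Site gains make desk-type activities wrist-dominant
(gain 2.5 at the wrist vs 0.9 at the hip) and locomotion hip/chest-
dominant with arm-swing amplification at the wrist (1.7) — the field's
known wrist behavior, and the mechanism by which applying a hip protocol
to wrist data degrades accuracy.

## What the generator does not emulate

Biomechanically faithful movement, device firmware quirks (idle sleep,
exact filter coefficients), non-wear, free-living behavior, posture
transitions within bouts, and heart rate. Passing tests therefore
demonstrate that the pipeline's logic is correct and that the classifiers
can exploit orientation/amplitude/covariate structure — not that the
specific accuracies would transfer to real laboratory recordings.

# Counts baseline

`raw_to_counts()` resamples each axis to 30 Hz, removes DC, band-passes
0.29–1.63 Hz (3rd-order Butterworth), rectifies, applies a 0.068 g
dead-band, saturates at 2.13 g, quantizes at 0.0164 g per count, sums per
second and aggregates to 60-s epochs. This follows the published
frequency-band approach to ActiGraph-style counts; exact firmware parity
is not claimed and every constant is config-exposed. Cut-points default to
the classical adult hip boundaries (100 / 1952 / 5725 cpm, vertical axis)
and the children's protocol rescaled to counts per minute
(100 / 2296 / 4012). The epoch length (60 s for both groups, the
children's native 15-s epoch available via config), axis choice and
rescaling behavior are all configuration, since none is uniquely
determined by practice.

`misspecification_report()` applies the hip protocols to counts from any
wear-site and tabulates per-epoch classifications against bout-level MET
truth as under / correct / over percentages by group × intensity (rows sum
to 100%), plus combined rows — the classical way this misspecification
penalty is reported. Epoch truth uses only epochs fully inside a bout
after trimming the first and final minute, and excluded bouts contribute
nothing.

# Windowing and splits

Recordings are segmented into 100-sample (1-s) windows tiled at a
configurable stride within each bout after trimming 60 s from each end.
The stride defaults to 100 (non-overlapping): with a random window-level
split, overlapping windows would place near-duplicates on both sides of
the split; overlap remains available via config. Windows never cross bout
boundaries and inherit the bout's intensity, the recording's site and the
participant's group/covariates. The rest period contributes no windows by
default.

Two split schemes exist: `window_random` (uniform over windows — the
historical scheme for this pipeline, kept as the default for fidelity) and
`by_participant` (whole participants, leakage-safe). The window-random
scheme leaks participant identity across the split, so its accuracies
should be read as within-sample; `by_participant` is recommended for any
generalization claim.

At the full study design (54 participants × 3 sites × 7 bouts of 5–8 min,
1-s windows) the pipeline produces windows on the order of 2–3 × 10^5^,
matching the scale reported for such protocols.

# Sequence classifiers

Both architectures operate on raw (100 × 3) windows in g — no gravity
removal, no hand-crafted features:

* `lstm`: one fully connected LSTM layer → dense ReLU layer with dropout
  → softmax output;
* `bilstm` (stacked): 1-D convolution → max-pooling → bidirectional LSTM
  → two LSTM layers → dense ReLU with dropout → softmax output.

When covariates are enabled, standardized age/height/weight are
concatenated to the final recurrent state ahead of the dense layer;
standardization always uses training-split statistics, which are stored on
the trained model and re-applied at prediction time.

The networks are implemented natively (RcppArmadillo: batched
backpropagation through time, Adam, global-norm gradient clipping, inverted
dropout). A single seeded generator drives initialization, shuffling and
dropout, so training is bitwise-reproducible; predictions break
probability ties toward the lowest class index.

Hyperparameters nowhere pinned down by practice are documented defaults,
selected by validation accuracy on the synthetic cohort the way any
practitioner would develop these models: 64 recurrent and dense units,
dropout 0.2 on the dense layer, 64 convolution filters of width 9, pool
size 3, batch 32, Adam at 1.5e-3 with cosine decay to 5% across the 20
training epochs. The wider convolution (90 ms) gives the front end enough
span to estimate local movement amplitude before pooling; pool size 3
shortens the recurrent unroll to ~30 steps, which is what makes 64-unit
recurrent layers affordable on one CPU core (a 20-epoch training on a
10^4^-window cohort runs in a few minutes); the cosine schedule lets the
fixed 20-epoch budget reach the accuracy plateau that a constant rate
only approaches; dropout stronger than 0.2 visibly underfits at this
budget. The cross-entropy target uses label smoothing of 0.1: window
labels inherit from bout-level MET estimates, so windows of bouts near
the 1.5/3/6 MET cut-offs are intrinsically ambiguous, and a smoothed
target stops the network from spending capacity memorizing that noise
(plain cross-entropy via `label_smoothing = 0`). Accuracy is reported at
the final epoch (best-epoch selection
available via config), and class frequencies are logged rather than
reweighted.

# Problem sizes used in tests and the acceptance script

* Cohort-statistics recovery: 500 synthetic participants per group,
  calorimetry only (a few seconds per 500 sessions).
* Counts baseline and network surrogates: one cohort of 12 participants
  (6 adult, 6 child) with hip and wrist recordings; ≈ 42k windows
  subsampled to 10,000; 90/10 window-random split; 20 epochs. The
  subsample fixes the training-problem size while leaving the bout and
  participant structure intact.
* Toy separability checks: 500–1000 windows of length 30 whose class is
  the sign of the channel-1 mean, with a closed-form threshold oracle as
  the independent reference, and a label-shuffled null at chance level.

The 2-SE acceptance bands on recovered MET means are exact statistical
bands, so individual runs sit inside them with ≈ 95% probability by
construction.

# Known limitations

* The generator's signal model is deliberately minimal; accuracies on it
  are upper bounds on what the same models would achieve on real
  recordings.
* The window-random split (the default, for fidelity) overstates
  generalization; use `by_participant` for honest out-of-sample claims.
* Count emulation approximates the published band-pass approach; no claim
  of firmware equality is made.
* The steady-state rule is a least-squares operationalization of a visual
  criterion; its tolerance is a judgment call, exposed in
  `gt_config()`.
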