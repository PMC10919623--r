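# wearsite

Wear-site-agnostic physical-activity measurement from raw accelerometry,
end to end: synthetic multi-site data generation, metabolic-equivalent
(MET) ground truth from indirect calorimetry, classical count/cut-point
baselines (including deliberate wear-site misspecification), and native
LSTM / Bi-LSTM sequence classifiers for wear-site detection and intensity
classification.

## The problem

Accelerometers are the workhorse of physical-activity research, but the
classical processing chain — device "activity counts" mapped to
sedentary / light / moderate / vigorous intensity via cut-points — is
calibrated to one wear-site (usually the hip). A participant who wears
the device at the wrist or on a chest lanyard, processed unknowingly with
a hip protocol, yields biased intensity estimates. `wearsite` implements
the modern alternative: deep sequence classifiers on raw 1-second
(100 × 3) acceleration windows that (a) detect the wear-site and
(b) classify intensity regardless of wear-site, optionally using
age/height/weight covariates.

The criterion measure is metabolic: a bout's MET value is its steady-state
oxygen uptake divided by resting uptake,

```
MET = VO2_steady / VO2_rest ,
```

with intensity classes `MET < 1.5` (sedentary), `1.5 ≤ MET < 3`
(light), `3 ≤ MET < 6` (moderate), `MET ≥ 6` (vigorous); boundaries
belong to the upper class. Resting VO2 is the mean over minutes 6–9 of a
10-minute seated rest, and steady state requires a trend-free window of
at least 3 minutes (quantified by a least-squares slope threshold).

Because no laboratory dataset is distributed, the package ships a
first-class synthetic-data module that generates cohorts, protocols,
multi-site 100 Hz signals and calorimetry with known latent ground truth;
every downstream stage is tested against those latents. See the methods
vignette (`vignettes/multisite-intensity.Rmd`) for the generator model and
all numerical choices.

## Worked example

```r
library(wearsite)

# 1. simulate a small cohort: 2 adults + 2 children, hip & wrist devices
coh <- simulate_cohort(2, 2, seed = 1, sites = c("hip", "wrist"))

# 2. MET ground truth per bout
gt <- lapply(coh$sessions, session_ground_truth)
gt[[1]]$bouts[, c("bout_index", "steady_vo2", "mets", "intensity")]
#>   bout_index steady_vo2     mets intensity
#> 1          1  14.878370 5.671010  moderate
#> 2          2   4.243812 1.617563     light
#> 3          3  18.638254 7.104120  vigorous
#> 4          4  16.055556 6.119704  vigorous
#> 5          5   3.208988 1.223131 sedentary
#> 6          6   4.073801 1.552762     light
#> 7          7   5.332894 2.032675     light

# 3. counts baseline: hip cut-points on hip vs (misspecified) wrist data
rh <- misspecification_report(coh$sessions, gt, applied_site = "hip")
rw <- misspecification_report(coh$sessions, gt, applied_site = "wrist")
round(c(hip = rh$overall_accuracy, wrist = rw$overall_accuracy), 3)
#>   hip wrist
#> 0.853 0.735

# 4. windows + a wear-site classifier (15,184 one-second windows here)
ws <- build_window_set(coh$sessions, sites = c("hip", "wrist"),
                       ground_truths = gt)
sp <- split_windows(ws, 0.9, seed = 2)
fit <- train_model(model_config("bilstm", "site2", epochs = 5, seed = 3),
                   sp$train, sp$validation)
tail(fit$history, 1)
#>   epoch train_loss train_acc   val_loss val_acc
#> 5     5 0.05317508         1 0.05102436       1
```

Epoch-level misclassification of the counts baseline concentrates where
the field expects it: the hip protocol applied to wrist-worn recordings
over-estimates sedentary and light epochs (desk activities move the wrist
a lot), and overall accuracy drops — here from 85.3% (hip-on-hip) to
73.5% (hip-on-wrist). The wear-site classifier separates hip from wrist
windows essentially perfectly on synthetic data, because the two sites
differ in static gravity orientation.

The ground-truth stage always assigns exactly 1.0 MET to the rest period
(the MET definition), bout labels inherit to all windows of the bout, and
excluded bouts (no steady state) contribute no windows.

A thin command-line wrapper over the same functions is installed at
`inst/cli/wearsite`:

```sh
Rscript inst/cli/wearsite all --config my_config.yaml --seed 7
```

with subcommands `simulate`, `groundtruth`, `baseline`, `windows`,
`train`, `evaluate`, `all`; artifacts are plain CSV/JSON stamped with the
configuration hash.

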