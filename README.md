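# dbmarker

Continuous digital biomarkers from sparse daily questionnaires in
addiction-monitoring eHealth systems — and everything needed to evaluate
them.

## The problem

Patients in treatment for alcohol use disorder answer a short daily
questionnaire (11 ordinal items on wellbeing, routines, stress, motivation
and self-confidence, coded 0–100) and perform scheduled breathalyzer tests.
Compliance is poor, and the missingness is *missing not at random*: losing
the motivation to answer is itself a warning sign of impending relapse. A
care provider looking at raw answers therefore sees long gaps exactly when
information is most needed.

`dbmarker` turns those sparse answers into two continuous indices defined on
every treatment day:

* **WeBe-i** — wellbeing, built from 9 questions;
* **MotSC-i** — motivation/self-confidence to stay sober, built from 2.

For each day, the raw daily value `x_t` is the mean of the available
contributing answers. Unanswered days are imputed by silence decay — with
`k` days since the last answered day,

```
x_t = (2/3) x_last   (k = 1)
x_t = (1/3) x_last   (k = 2)
x_t = 0              (k >= 3)
```

— and the biomarker is the exponentially smoothed series

```
S_0 = x_0,   S_t = alpha * x_t + (1 - alpha) * S_{t-1},   0 < alpha < 1
```

with `alpha = 0.32` by default. The question grouping is derived from data:
correlation-matrix PCA on complete patient-days, varimax rotation, and
assignment of each question to its dominant factor.

Downstream, the package detects exacerbation events (runs of >= 2 days with
alcohol detected or all tests omitted), labels days whose 1–3 or 5–7 day
look-ahead window contains an event start, filters to eligible days (past
the 7-day start-up, not already in an event, sobriety index >= 40), windows
7–93 days of history, splits patients 70/15/15 into train/validation/test,
trains a masked-sequence LSTM (implemented natively, no deep-learning
dependency), and reports AUC plus sensitivity/specificity/MCC at the
MCC-maximizing threshold. A synthetic-cohort generator with a 3-state
latent Markov chain (stable / deteriorating / in-event) reproduces the
statistical structure the method assumes, so the whole pipeline runs and is
tested without clinical data.

## Worked example

```r
library(dbmarker)

cfg <- pipeline_config(
  simulate   = synth_config(n_patients = 100, days = 120, seed = 1),
  feature_set = "biomarker2",          # the two digital biomarkers
  look_ahead  = c(1, 3),               # predict event starts 1-3 days ahead
  forecaster  = forecaster_config(hidden = 16, max_epochs = 6,
                                  patience = 6, seed = 1),
  seed = 1, out_dir = "runs/demo")
res <- run_pipeline(cfg)
#> [dbmarker] simulate: 100 patients x 120 days
#> [dbmarker] inputs: 93984 answers, 12000 sobriety days
#> [dbmarker] samples: 10561 (302 positive) from 100 patients
#> [dbmarker] split: train=7349, validation=1625, test=1587
#> [dbmarker] train: 6 epochs, best at 5
#> [dbmarker] evaluate: test AUC 0.774, MCC 0.289 at threshold 0.672
res$report
#> <metrics_report> n = 1587
#>   AUC 0.774 | threshold 0.6715 | MCC 0.289
#>   Sensitivity 0.086 | Specificity 1.000 | TP 5 TN 1529 FP 0 FN 53
```

The test AUC of 0.77 says the two smoothed indices alone carry real
advance warning of simulated exacerbation events on unseen patients. With
positives under 4% of eligible days the MCC-maximizing threshold lands at a
very conservative operating point (few, almost certain alarms) — MCC
rewards precision heavily at this prevalence, which is exactly why the
threshold is swept rather than fixed at 0.5. `runs/demo/`
contains tidy CSVs (biomarkers, events, labels, per-sample predictions),
the metrics table and a JSON manifest (seed, config hash) that makes the
run byte-reproducible.

Individual stages are plain functions: `build_day_grid()`,
`build_biomarker()`, `principal_components()` / `varimax_rotate()` /
`assign_questions()`, `detect_exacerbation_events()`, `make_labels()`,
`eligibility_mask()`, `make_samples()`, `split_patients()`,
`train_forecaster()`, `best_mcc_threshold()`, `plot_patient()`. A thin CLI
lives at `inst/scripts/dbmarker-pipeline.R`.

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline (simulate → code →
biomarkers → events → samples → train → evaluate) from scratch under a
given seed and writes its results manifest:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
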