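---
title: "From sparse daily questionnaires to continuous digital biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sparse daily questionnaires to continuous digital biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbmarker)
```

## The model

Daily self-report in addiction care is sparse, and the sparsity is
informative: a patient drifting toward relapse stops answering. `dbmarker`
treats a questionnaire biomarker as the exponentially smoothed output of a
two-stage daily process.

**Stage 1 — raw daily value.** For a biomarker defined by a question subset
$Q$ (WeBe-i uses 9 wellbeing items, MotSC-i the motivation and
self-confidence items), the raw value on day $t$ is the mean of the coded
answers to the members of $Q$ available that day. If no member was
answered, the value is imputed from the silence itself: with $k$ days since
the last answered day, $x_t = \tfrac{2}{3}x_{\text{last}}$ for $k=1$,
$\tfrac{1}{3}x_{\text{last}}$ for $k=2$, and $0$ for $k \ge 3$. The
imputation encodes the working hypothesis that non-compliance correlates
with a worsening state; three days of silence are treated as a full loss of
the signal.

**Stage 2 — smoothing.** $S_0 = x_0$ and
$S_t = \alpha x_t + (1-\alpha) S_{t-1}$. The index therefore carries
"historic baggage": one answer influences the next days with geometrically
decaying weight, and during total silence the index decays by a factor
$(1-\alpha)$ per day once the raw value has reached 0.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.32 | weight of today's raw value; 0.32 makes the questionnaire indices visually commensurate with the breathalyzer-based sobriety index. The historical alternative 0.21 reacts so slowly that only missing-data dips remain visible. Units: none; domain $(0,1)$. |
| decay fractions | 2/3, 1/3, 0 | imputed fraction of the last observed raw value on the 1st, 2nd and $\ge$3rd silent day. Fixed by the construction, not exposed as tuning knobs. |
| `ami_min` | 40 | eligibility floor on the 0–100 sobriety index: days already at rock-bottom compliance need no forecast. Inclusive boundary. |
| `startup_days` | 7 | leading treatment days excluded from forecasting (start-up period). |
| `min_hist`, `max_hist` | 7, 93 | window of daily feature vectors fed to the sequence model, ending at (and including) the anchor day. |

### Choices the design left open

* **Series start.** "Days since the last answered day" is undefined before
  the first answer, so each biomarker series starts at the subset's first
  observed raw value; earlier panel days carry `NA` (provenance
  `"undefined"`). No prior is invented.
* **Inactive tails.** Only *leading and trailing* runs of days with neither
  an answer nor a sobriety record are trimmed from a patient's calendar
  grid. Interior gaps are retained — they are the signal the imputation
  exploits. Sobriety records count as activity.
* **Treatment periods.** Panels are built per contiguous recording span; a
  patient with several treatment periods restarts the series per period
  (smoothing never bridges an inactive tail).
* **Same-day breathalyzer collapse.** Several tests on one day collapse to
  one status with precedence detected > performed > omitted, so one
  positive test marks the day and `all_omitted` means literally all tests
  skipped.
* **Eligibility timing.** The AMI threshold uses the same day's index
  value, and the look-ahead window is $[t+\mathrm{lo}, t+\mathrm{hi}]$ —
  strictly after the anchor day, so features and labels never share a day.

## Question grouping

The grouping of the 11 items into two biomarkers is re-derivable from data:
correlation-matrix PCA on complete patient-days only, Kaiser retention
(eigenvalue > 1), varimax rotation with Kaiser row-normalization
(tolerance 1e-6), and assignment of each question to the factor holding its
largest absolute rotated loading (ties to the lowest factor index; column
signs fixed so each factor's dominant loading is positive). The default
merge map combines factors 1 and 3 into the wellbeing index and keeps
factor 2 as motivation/self-confidence: the third factor collects exactly
the three 3-alternative questions (Exercise, Socialized, Angry), a
discretization artifact rather than a clinically distinct dimension, and
merging it into wellbeing reproduces the deployed grouping. PCA on the
correlation rather than covariance matrix standardizes away the wider
spread of the 3-alternative items.

## Forecasting

Three per-day feature layouts are compared under an *identical, untuned*
network: `raw22` (11 answers, missing filled with 0, plus 11 answered
indicators), `avg4` (the two subset means plus answered indicators) and
`biomarker2` (just MotSC-i and WeBe-i, rescaled to $[0,1]$). Equal
performance of `biomarker2` indicates the biomarker transformation loses no
predictive information. The fill value 0 for missing raw answers is
disambiguated by the indicator channel; biomarker features need no
indicator because the construction defines them everywhere.

The classifier is a single-layer LSTM (32 hidden units by default, dropout
0.2 on the final hidden state, sigmoid head) trained with class-weighted
binary cross-entropy (weights inversely proportional to prevalence), Adam
at 1e-3, batch 64, early stopping on validation loss with patience 10. No
deep-learning framework for R exists in the deployment environment, so the
forward pass, backpropagation through time and Adam are implemented in
compiled code inside the package; windows shorter than the longest in a
batch are padded at the *old* end and a mask makes padded steps carry the
recurrent state through unchanged, which is exactly equivalent to starting
the recursion later. Training is single-threaded and bitwise reproducible
given a seed. Splits are by patient — 70/15/15 by default, or exact counts
— so test patients are never seen in any form during training.

Evaluation reports rank-based AUC (ties one half) on the per-day
probability, then sweeps every threshold that can change the confusion
matrix (midpoints of sorted unique probabilities plus 0 and 1), with the
prediction rule `probability >= threshold`, and reports
sensitivity/specificity/MCC at the MCC-maximizing threshold (ties toward
the smallest threshold; MCC defined as 0 when a denominator factor
vanishes). Rounding to 3 decimals happens only at reporting. Thresholds
are selected on the test predictions to mirror the published evaluation
design; the validation-selected variant is also computed.

## The synthetic cohort: what it emulates, what it does not

The generator gives each patient a 3-state latent chain — stable,
deteriorating, in-event — with daily transitions (defaults: stable to
deteriorating 0.02, deteriorating to event 0.15, deteriorating back to
stable 0.10, event to stable 0.30). The state drives three observable
channels:

* **engagement** — answering-day probability 0.9 when stable, multiplied
  by 1/3 when deteriorating and 0.25 in-event, so missingness is MNAR by
  construction;
* **answer levels** — stable-state means per question near those seen in
  AUD monitoring cohorts (e.g. Angry 91, Motivation 89, Exercise 54),
  shifted by −30 when deteriorating and −40 in-event, with an extra −10 on
  Motivation/SelfConf; a Gaussian with SD 20 is snapped to the question's
  ordinal grid;
* **breathalyzer** — in-event days are always relapse-indicating (alcohol
  detected with probability 0.5, otherwise all tests omitted); non-event
  days omit all tests with small probability (0.03 stable, 0.10
  deteriorating).

These defaults are the package's single stated world: a deterioration
prodrome of about a week, one to two events per patient over four months,
and positives making up a few percent of eligible days. The generator does
*not* emulate inter-patient heterogeneity of answer styles (cultural or
idiosyncratic Likert usage), weekly periodicity, dropout/censoring, or any
demographic structure. A green forecasting test therefore establishes that
the pipeline recovers a planted MNAR + level signal end to end — not that
clinical data carries a signal of that size; the null-signal configuration
(`null_signal_config()`), which zeroes the questionnaire's dependence on
the state while keeping events, establishes that no signal is manufactured
by the machinery itself.

## Numerical choices

Double precision throughout; biomarker equality tests use tolerance 1e-9.
The smoothing recursion is evaluated by a compiled linear filter with the
initial condition pinned to $S_0 = x_0$. Varimax convergence tolerance is
1e-6; PCA eigenvalues are clipped at 0 before taking square roots.
Zero-variance columns are an error in PCA rather than silently dropped.
The MCC sweep is exact, not grid-based. The LSTM uses forget-gate bias 1,
uniform $\pm 1/\sqrt{H}$ initialization, and a fixed Mersenne-Twister
stream decoupled from R's RNG; `split_patients()` and the simulator save
and restore R's RNG state so library calls never perturb a session's
stream.

## Test and acceptance budgets

The automated forecasting checks run the full 300-patient × 120-day
cohorts but scale the *training budget* down (16 hidden units, 6 epochs)
so the suite fits a single-CPU desk budget; the strong-signal AUC
comfortably clears its bound within that budget, and results at the default
32/100 configuration are only better. The acceptance script simulates 150
patients for the same reason. The null-signal check treats the chance band
[0.45, 0.55] as a per-seed assertion; with roughly 45 held-out patients the
AUC estimate has a standard error of a few hundredths, so an individual
seed can graze the boundary — the suite reports one such graze (0.4499 on
the third null seed) as a plain failure rather than widening the band.

## Known limitations

* The sobriety index used for eligibility is an explicit approximation of
  the deployed Addiction Monitoring Index (same mechanics, breathalyzer
  coding 100/0/missing); recorded AMI values are preferred whenever the
  input provides them.
* Exact-count splits reproduce published cohort partitions only when the
  patient count matches.
* The LSTM is deliberately minimal: one layer, no attention, no tuning —
  matching the design that all feature sets share one untuned network.
* Events are defined from daily status only; mixed days (some tests
  omitted, some passed) count by their collapsed daily status, so a day
  with one passed and one omitted test is a `no_alcohol` day.
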