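---
title: "Calibrating PIR motion-sensor systems with wearable data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating PIR motion-sensor systems with wearable data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ambcal)
```

## The measurement problem

A body-worn accelerometer measures each activity $a_i$ on a
person-independent intensity scale, $f_{acc}: A \to \mathbb{R}_+$. A
PIR motion-sensor system measures the same activities through a binary,
layout-dependent channel $f_{PIR}$: whether and for how long motion is
detected depends on sensor placement, angle, distance and room
geometry, so raw PIR "activity" is not comparable across apartments,
and activities outside the sensors' domain (outings, blind spots) are
missed entirely — the PIR system only ever observes a restricted
activity set $\tilde A \subseteq A$. Calibration seeks
$\hat f_{PIR}: \tilde A \to \hat M_{PIR}$ minimizing the squared
distance to the domain-restricted accelerometer measurement
$\tilde f_{acc}$, i.e. an ordinary regression of wearable activity on
PIR-derived features. Once $\hat f_{PIR}$ is fitted, the wearable can
be retired: the ambient system alone reports activity on the wearable
scale.

`ambcal` implements this pipeline end to end: island extraction,
per-participant calibration with predictive uncertainty, outing
detection and imputation, and the evaluation battery. This vignette
records the modelling assumptions and every place where the design was
genuinely open.

## Activity islands and features

The per-second **total PIR signal** counts the sensors active at each
second. PIR events are stored as state changes; a sensor is active from
an on-event to its next off-event. The signal is smoothed with a
1-minute simple moving average and islands are the maximal runs of
strictly positive smoothed signal.

Numerical choices:

* **Window alignment.** The moving average is *centered*, with the
  window shrinking symmetrically at the edges. A trailing window would
  shift island boundaries ~30 s late relative to the motion that caused
  them; a centered window keeps island onset aligned with bout onset.
* **Grid.** Everything is computed on a 1 s grid — the native wearable
  rate; a 0.5 Hz binary sensor upsamples to it losslessly under the
  hold semantics.
* **Features** per island: total duration (s), integer local hour of
  the island start (a single scalar, no circular encoding — islands
  cluster in the daytime, so the wrap-around discontinuity at midnight
  is immaterial and a scalar keeps the linear kernel interpretable),
  per-room PIR-active seconds (union over the room's sensors), and
  per-room activity relative to the *island duration* (not to the sum
  of room durations; rooms can co-trigger, so the per-room relative
  activities need not sum to one and are reported unclipped).
* **Targets.** The accelerometer magnitude summed over the island
  interval. Islands whose interval has less than 80% wearable coverage
  get a missing target and are excluded from calibration and from
  MAE/ρ̃ evaluation; partially worn islands would otherwise bias
  targets low. The 80% threshold is a package choice, exposed as
  `min_coverage`.
* **Standardization** uses per-column mean and *population* standard
  deviation learned on the calibration islands only; evaluation
  islands are transformed with the calibration statistics (no
  leakage). Constant columns are dropped and recorded.

## The calibration model

The primary learner is Gaussian process regression with

$$k(a_i, a_j) = \sigma_0^2 + a_i \cdot a_j + \sigma_n^2 \delta_{ij},$$

a constant term plus dot product plus white noise on the standardized
features — equivalently, Bayesian linear regression with an unknown
intercept scale. Two conventions deserve note:

* **Term roles.** We attach the white-noise role to the
  $\delta_{ij}$ coefficient $\sigma_n^2$ (it is the only term that can
  act as independent per-observation noise) and treat $\sigma_0^2$ as
  the constant (bias) variance. Descriptions that label these two the
  other way around conflict with the algebra of the kernel itself.
* **Target scale.** The GP prior has zero mean on the *standardized*
  activity scale: targets are centred and scaled inside the fit and
  predictions are transformed back. Without this, the parameter-free
  dot-product kernel (variance $O(p)$ on standardized features) could
  not express targets whose variance is in squared activity counts.

$(\sigma_0^2, \sigma_n^2)$ are chosen by maximizing the log marginal
likelihood with L-BFGS-B on the log scale from 5 seeded restarts; ties
are broken by the higher likelihood, then the smaller $\sigma_n^2$.
Because the kernel is low-rank, the likelihood, posterior mean and
posterior variance are computed through the Woodbury identities in
$O(np^2)$ rather than $O(n^3)$; the test suite checks this low-rank
path against an independently coded dense conditional-Gaussian oracle
to $10^{-8}$. The reported predictive standard deviation is that of the
marginal normal *including* the white-noise term, so it is the
uncertainty of a new island's measured activity, not of the latent
mean. Predicted means are clipped at zero in reports and daily sums
(targets are non-negative); raw means are retained internally.

Baselines: ordinary least squares (no hyperparameters), and
gradient-boosted trees via xgboost with random search (default 25
draws) over depth 2–6, learning rate 0.01–0.3 (log-uniform), 50–500
trees, subsample 0.5–1 under 3-fold cross-validation. For cohort use,
`search_hyperparams()` splits the folds *at the participant level*:
one pooled model per fold split is scored on held-out participants
(with per-participant target standardization so large apartments do not
dominate), and the selected shared hyperparameters are then used for
the per-participant fits. Fits are deterministic given the seed, and
wear-time curves re-run the search per calibration-duration point.

## Outings, τ, and imputation

An **outing** is the interval between an entrance-door event and the
next entrance-door event with no PIR motion anywhere in between, at
least 5 minutes long (threshold exposed; shorter door-to-door gaps are
household door use). The entrance stream is first cleaned to alternate
open/close by dropping repeated states.

The **temporal profile** bins the clock into 30-minute intervals
(width exposed) and averages at-home activity per second over observed
days, one day-mean per bin per day; days where a bin is entirely
unobserved are excluded from that bin's support, and bins supported by
fewer than 3 days are flagged. For each outing with at least 80%
wearable coverage, the per-second wearable activity is divided by the
profile expectation over the same clock interval — per-second rates, so
outings of unequal length compare fairly — and the median ratio is
$\tau_p$; the cohort mean of the $\tau_p$ is the global $\tau$. By
default $\tau_p$ is estimated from the calibration window only (the
wearable is not assumed available later); a flag allows all wear data.
Weekday structure is not modelled: all days pool into one profile.

**Imputation** adds, for every outing second, the temporal-mean
expectation of *calibrated* at-home activity times a factor — 1, τ_p,
or τ. Using the calibrated profile (not the wearable's) keeps the
imputed series a pure function of the ambient system plus the single
scalar τ_p, so evaluation against the wearable stays honest. Seconds
between islands count as zero in that profile, since the calibrated
series is zero there.

## The synthetic home

No public dataset couples PIR streams with wearable ground truth, so
the generator is a first-class module and the package's tests are
parameter-recovery experiments against it. It emulates:

* alternating rest/active bouts in a waking window (07:00–23:00):
  exponential inter-bout gaps (rate `bout_rate`, default 2/waking
  hour), log-normal durations (480 ± 300 s), per-bout intensity =
  base level (8 counts/s) × log-normal level noise (CV 0.4) × a
  24-point diurnal profile × a per-day log-normal scale (sd 0.15)
  capturing day-to-day behavioural variability;
* room choice per bout from a preference distribution over the
  standard layout (kitchen, toilet, living room, entrance, bedroom,
  bathroom);
* an abstract PIR response: per bout, a room's sensor either misses it
  entirely (dead-zone probability, default 0.08) or detects a
  contiguous fraction $1 - e^{-g I}$ of it (gain $g$ per room, default
  0.08), with a 4 s trigger hold and 2 s refractory period — this
  reproduces the angle/distance/layout distortions that make raw PIR
  durations incomparable across apartments. A deterministic `linear`
  response mode (detected seconds exactly $\min(1, gI) \times$
  duration, emitted as short pulses across the bout) makes the target
  an exact linear function of the features and is used to validate the
  calibration chain;
* door-bracketed outings (Poisson, default 1/day, 90 ± 30 min,
  daytime) during which all indoor sensors are silent and the wearable
  records `tau_true` times the participant's *realized* mean at-home
  intensity at that clock hour — so the generated series' true
  outside/inside ratio equals `tau_true` by construction; bouts
  overlapping an outing are clipped at its boundaries rather than
  dropped, which would otherwise create artificial rest time around
  outings and bias the at-home baseline;
* overnight non-wear: the wearable records only 07:00–22:00 local
  time, plus additive truncated-Gaussian noise (sd 0.25 counts). The
  sd is deliberately small relative to bout intensity (~3%): truncation
  at zero inflates the measured rest baseline by ≈ 0.4·sd per second,
  and real wearables report near-zero counts at rest; keeping the sd
  small keeps this truncation bias second-order in the τ estimator.
* cohort heterogeneity: per-participant log-normal multipliers on
  sensor gain (sd 0.4), bout rate (0.2) and intensity (0.25), and
  `tau_true` uniform on [0.9, 1.8] — the spread reported for
  community-dwelling older adults.

All randomness flows from one root seed through named substreams, so
mechanisms are coupled: raising a sensor gain with the seed fixed can
only add detected seconds, which the tests exploit as a monotonicity
property.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: multi-person households and pets, sensor
hardware faults and radio dropout, wearable non-wear at arbitrary
times, seasonal behaviour change, GPS-verifiable outings, and genuinely
non-linear PIR responses beyond the saturating family. Recovery of τ
or of calibration quality on real homes can be worse in all of these
directions.

## Evaluation battery

Metrics follow the per-participant / global two-level scheme: island
MAE and its daily mean; ρ (daily predictions vs *full* wearable daily
totals, outings included) and ρ̃ (vs island-restricted totals); global
values are unweighted participant means. Days are bounded by local
midnight (day boundaries are otherwise arbitrary); days with fewer than
2 islands are excluded from daily correlations; zero-variance daily
series yield missing correlations rather than zeros, which would bias
global averages toward the null.

The drift analysis standardizes each participant's weekly MAE series
robustly (median removed, scaled by IQR; zero-IQR participants are
excluded with a warning), averages across participants per week
(unweighted — weighting by available participants is a reasonable
alternative we did not take), and tests the OLS slope over the week
index two-sided at α = 0.05. Weekly bins are 7 consecutive calendar
days from the end of calibration.

The clinical comparison correlates (Spearman) median daily activity
totals from three sources — raw PIR island durations (pre-calibration),
calibrated daily totals (post), and the wearable — with the
per-participant mean of each assessment, then applies the one-sided
Wilcoxon signed-rank test to the |r| pairs under the alternative that
calibration increases them. The test is exact by permutation for
n ≤ 25 non-zero differences without ties (eight all-positive
differences give exactly p = 1/256 ≈ 0.0039) and falls back to the
normal approximation with continuity correction otherwise.

## Problem sizes

The test-suite Monte-Carlo experiments run at sizes chosen to make each
property decidable in minutes on one core while preserving the study
design (30-day calibration reserve, evaluation beyond day 30, ≥ 60 days
per participant where the full split matters): 60-day single homes for
calibration recovery (5 seeds), 5-home 60-day cohorts for the wear-time
curves (5 seeds), 30-day homes for τ recovery (10 seeds × 3 τ values),
60-day homes for the imputation-mode ordering (10 seeds × 2 homes), and
6-home 40-day cohorts for the clinical harness (10 seeds). The drift
size/power check generates stationary (and linearly drifting) weekly
MAE series directly, since it is a property of the slope test, not of
the simulator. `scripts/acceptance.R` uses a 6-home, 90-day cohort —
90 days so the weekly drift regression has its required ≥ 8 evaluation
weeks — and summarises the clinical comparison over 5 replicate 6-home
cohorts, since a single 6-home draw of that statistic is dominated by
sampling noise.

## Known limitations

* Single-occupant homes only; a second person (or pet) breaks the
  identification of PIR activity with the wearer.
* The calibrated scale is only as comparable across participants as
  the wearable's own intensity scale.
* Activities invisible to the PIR system (outside sensor coverage)
  remain unmeasured after calibration; imputation corrects outings
  only, and with a deliberately coarse one-factor model.
* τ estimation needs outings during the calibration window with
  wearable coverage; housebound participants yield an undefined τ_p
  and must fall back to the global τ.
* The hour-of-day feature is apartment-local clock time; shift work or
  highly irregular schedules weaken both the feature and the temporal
  profiles.
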