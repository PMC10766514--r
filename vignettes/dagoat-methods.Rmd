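---
title: "Methods: the daGOAT dynamic risk model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the daGOAT dynamic risk model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dagoat)
```

## The problem and the model

After allogeneic hematopoietic stem cell transplantation, patients are
monitored through a large panel of dynamic clinical variables whose
sampling is heterogeneous: vital signs near-daily, flow-cytometric
immune profiles rarely and not for everyone. The modelling target is a
daily-updated score for the risk that severe acute graft-versus-host
disease (aGVHD) onset — operationally, the day aGVHD treatment is
initiated — occurs within the next δ days.

The score for patient $i$ at day $t$ is

$$\varphi_i(t) = \rho(\mathbf{z}_i) + \sum_{\tau = t-\delta+1}^{t}
\sum_k I_{ik\tau}\,\theta_k\!\left(x_{ik}(\tau), \tau\right),$$

a sum of a static prior and of per-cell contributions over the trailing
δ-day window. Three assumptions drive the design:

1. **Non-stationarity.** The same laboratory value can mean different
   things on day 5 and day 50, so $\theta_k(\cdot, t)$ is a function of
   time, not a single coefficient.
2. **Smoothness in time.** The biological process is assumed to drift
   smoothly, so the per-day estimates of a variable's class-conditional
   bin probabilities are pooled across neighboring days by smoothing
   splines. This is what lets a sparsely measured variable contribute
   on days where it was almost never observed.
3. **Missingness as absence of evidence.** A missing cell contributes
   exactly zero ($I_{ik\tau} = 0$). No interpolation is performed in
   the raw-data space — value distributions across heterogeneous units
   are unknown, so interpolation happens only in probability space
   (assumption 2). The only raw-data densification is the time-limited
   sample-and-hold (below), which reflects how long a measurement stays
   clinically valid, not a statistical imputation.

Fitting proceeds in four steps, deterministic given data and
configuration:

1. $\rho(\mathbf{z})$ is the log-odds of a categorical Naive Bayes
   classifier over the peri-transplantation features, fitted once
   against the static outcome "onset within the horizon" (it is a
   baseline-risk term, not a time-varying one). Additive smoothing uses
   pseudocount 1; a category unseen in training receives the
   zero-count smoothed probability in both classes, keeping scores
   finite.
2. For every variable $k$ and day $t$, the cutoff $c_{kt}$ maximizing
   Shannon mutual information between $\{x > c\}$ and the windowed
   outcome is searched over the midpoints of consecutive distinct
   observed values; the discretization thresholds $l_k, u_k$ are the
   25th/75th percentiles (linear interpolation, R type 7) of the
   defined per-day cutoffs.
3. Per day, the class-conditional probabilities of the low
   ($x < l_k$) and high ($x > u_k$) bins are observed fractions among
   risk-set patients with the variable measured that day; days with no
   observed patient of a class leave that class undefined.
4. Each probability series is smoothed along the day axis with a cubic
   smoothing spline whose smoothness is chosen by generalized
   cross-validation, evaluated at every integer day of the horizon
   (extrapolating at the ends). Spline output may stray outside
   $[0,1]$; it is clamped at zero inside $\theta$ before the floor
   $\gamma$ is added, and the middle bin uses
   $\max\{0,\,1 - \rho^{(L)} - \rho^{(H)}\}$ per class.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `delta` | 14 | days | forecast window; the score targets onset in $(t, t+\delta]$. Two weeks matches the clinically actionable horizon for prophylaxis intensification. |
| `gamma` | 0.1 | probability | floor added to numerator and denominator of every bin-probability ratio; bounds any single cell's contribution by $\log((1+\gamma)/\gamma)$ and shrinks sparse-day estimates toward zero. As $\gamma \to \infty$ all dynamic contributions vanish and $\varphi \to \rho(\mathbf{z})$. |
| `smoothing` | `TRUE` | — | use spline-smoothed probability curves; with `FALSE`, raw per-day estimates are used and a day with undefined estimates contributes zero (no information, no contribution). |
| `horizon` | 100 | days | last day modelled; label windows near the horizon are capped at it. |
| `hold_days` | 3 | days | sample-and-hold validity span: an observation is carried forward up to three days unless overwritten, never past a patient's last observed day. |
| NB `pseudocount` | 1 | counts | additive smoothing of the peri-feature conditionals. |

## Conventions where the method is under-determined

Several details admit more than one reasonable reading; the package
fixes them as follows (each is exercised by a test):

* **Candidate cutoffs and ties.** Candidates are midpoints between
  consecutive sorted distinct values; mutual-information ties go to the
  smallest candidate, making fits reproducible bit-for-bit.
* **Minimum class support.** A day's cutoff requires at least one
  observation per outcome class; otherwise the day is excluded from the
  $l_k/u_k$ percentile pool. A variable with no defined cutoff on any
  day is flagged uninformative and contributes $\theta \equiv 0$.
* **Sparse probability series.** Fewer than four defined days cannot
  support a cubic smoothing spline; the series falls back to the
  constant mean of the defined values, and an all-undefined series
  contributes zero.
* **Early and late windows.** For $t < \delta$ the scoring window
  truncates at day 1; outcome windows cap at the horizon, so labels
  near the end use onset $\in (t, \min(t+\delta, \text{horizon})]$.
* **Risk-set labels.** Patients who leave observation (death,
  discharge) before onset count as non-events while in the risk set and
  leave it after their last observed day.
* **Ordering of preprocessing.** Same-day replicate measurements are
  averaged first; sample-and-hold runs on the daily panel afterwards.
* **Aggregation windows vs. contribution windows.** $\varphi_i(t)$ sums
  $\theta_k(\cdot, \tau)$ terms whose probabilities were estimated
  against the window anchored at $\tau$, exactly as the score is
  written; no re-alignment to the window anchored at $t$ is attempted.

## Evaluation machinery

Daily AUROC uses midrank tie handling; AUPRC is average precision with
step interpolation (ties enter as blocks, so constant scores give the
prevalence). Confidence intervals are percentile bootstrap over
patients (default 1,000 resamples; single-class resamples are skipped).
The sextile hazard ratio dichotomizes day-$t$ scores strictly above the
5/6 quantile and fits an unadjusted Cox model on onset within
$(t, t+\delta]$, censoring at the window end; a group with zero events
makes the ratio incalculable and is flagged rather than forced.

Internal validation uses expanding-window temporal cross-validation:
patients in cohort (temporal) order are cut into `n_folds` blocks; fold
$j$ trains on blocks $1..j{-}1$ and validates block $j$. Out-of-fold
scores are pooled before computing daily metrics, so each day's metric
uses all validated patients at once. The first block is never validated
(it has no preceding training data); metrics therefore describe the
post-seed cohort.

Feature importance at day $t$ is the decrement in pooled out-of-fold
AUPRC when a feature is removed from fitting and scoring entirely;
features are ranked by their maximum importance over days 8–30 (ties
alphabetical). Data density is the fraction of available cells per
feature over days 1–30 after sample-and-hold. The 2×2 χ² test applies
the Yates continuity correction by default (each observed count moved
toward its expectation by 0.5, never past it).

Benchmarks: the peri-features-only models reuse the Naive Bayes
implementation and a Random Forest (library defaults, 500 trees, fixed
seed); XGBoost receives one column per (feature, lag) pair over the
δ-day window with unobserved cells as native missing values, and the
recorded defaults `objective = binary:logistic`, `eta = 0.3`,
`max_depth = 6`, `nrounds = 50`, single-threaded with a fixed seed. No
hyperparameter search is performed for any model.

## What the generators emulate — and what they do not

**Binary-state scenario generator.** Each of $p = 50$ features follows
a symmetric two-state random walk over $T = 14$ days (stay 0.7, switch
0.3, initial state uniform — the chain's stationary law). Effector
features ($k \le 45$ in the complex condition, $k \le 5$ in the simple
one) carry a time curve $\alpha_k(t)$ — a multiplicative Gaussian
random walk (step mean 1, sd 0.05) when smooth, i.i.d. uniform when
rough — linearly rescaled so its minimum is exactly 0.3 and maximum
exactly 0.7, giving $\theta_k(\text{high}, t) =
\log(\alpha_k/(1-\alpha_k))$ and $\theta_k(\text{low}, t) =
-\theta_k(\text{high}, t)$; dummies have $\theta \equiv 0$. The
relative risk $\varphi_i = \sum_t \sum_k \theta_k(x_{ik}(t), t)$ is
compared literally against a uniform(0,1) draw — values $\le 0$ can
never fire, values $\ge 1$ always do; no logistic transform is applied.
Cohorts are oversampled in batches (capped at 100×) and downsampled
without replacement to exactly 15% positives at $n = 1{,}000$;
missingness (0 or 60% of cells, uniform at random) is applied **after**
event assignment, since events depend on the complete trajectories.
Scenario replicates use seeds derived deterministically from the base
seed, scenario index and replicate number. For model fitting, a
simulated cohort maps to the clinical container by giving positives a
nominal onset at day $T{+}1$ (with an all-missing trailing day so the
onset lies inside both the observation span and, with $\delta = T$,
every day's label window) — the moving-window label then equals the
static event indicator on every day, as the single end-of-series
outcome requires.

**Clinical fixture generator.** Continuous trajectories
$x_{ik}(d) = \mu_k + \sigma_k(0.8 L_{ik} + 0.6 e_{ik}(d))$ with
patient-level latent levels and AR(1) day noise; onset days are drawn
from a discrete-time hazard $h_i(d) = h_0(d)\exp(\sum_k \beta_k
z_{ik}(d))$ with a bell-shaped baseline peaking near day 25 (the
reported adult onset quartiles center there) and peak daily baseline
hazard 0.004, giving roughly a fifth of patients an onset — in line
with reported severe-aGVHD rates. Defaults designate one strong
effector (`crp`, $\beta = 1.5$ per SD) among eight routine variables
sampled at realistic frequencies (0.15–0.95 per day); a tenth of
event-free patients are discharged early. Ground truth (effect sizes,
latents, baseline hazard) is returned for recovery tests.

Neither generator reproduces several features of real transplant data:
informative missingness (sicker patients are measured more), measurement
error and unit drift across years, correlated feature blocks (a blood
count arrives as a panel), competing risks (death before onset is
plain censoring here), or peri-feature confounding beyond a single
mildly associated category. Passing recovery tests on these generators
therefore shows the algorithmic machinery is correct and directionally
sensible — not that clinical performance on any real cohort is
reproduced.

**Activity-dataset adapter.** The smartphone
activities/postural-transitions dataset is consumed as published
(561 features per 1.28-s window, fixed subject-level train/test split).
Segment extraction enumerates every offset of each run of 7 consecutive
sitting windows (stride 1) and labels a segment positive when any of
the next 4 windows carries the sit-to-stand code; a lookahead truncated
by the end of a recording uses whatever windows remain. Converted
segments become 7-day pseudo-patients with $\delta = 7$, so the scoring
window spans the whole segment and the prior reduces to the class-prior
log-odds. The dataset itself is not redistributable inside the package,
so the printed-count check runs only when a local copy is present.

## Numerical choices and degenerate inputs

* Percentiles everywhere use R's default type-7 linear interpolation.
* `smooth.spline` occasionally fails on near-degenerate series; the
  implementation falls back to the constant mean in that case.
* Model serialization writes every numeric with 17 significant digits,
  so a reloaded model reproduces trajectories exactly.
* Empty cohorts, all-missing features, single-class days, zero-margin
  tables and sub-sextile risk sets all return explicit markers
  (`NA` / `uninformative` / `incalculable`) rather than errors, except
  where the operation is meaningless (fitting with zero events).
* Scores are translation-covariant: shifting all data, onsets and the
  horizon by a constant number of days shifts trajectories identically
  — day indices are bookkeeping, not model inputs.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the scenario comparisons
at $n = 1{,}000$ with 30 replicates (daGOAT vs XGBoost) and 20
replicates (smoothing ablation) in the smooth + complex +
60%-missingness condition, oracle-agreement sweeps at 1,000 random
instances, and fixture recovery at $n = 500$; these sizes give stable
directions and complete in about a minute each on one CPU. The full
2×2×2 scenario grid at 150 replicates per cell remains available
through `run_scenario_grid(scenario_grid(), reps = 150)` or the CLI
`simulate` subcommand as a long-running command.

## Known limitations

* The peri prior assumes conditional independence of categorical
  features; continuous peri features must be discretized upstream.
* $\varphi$ is a relative score, not a calibrated probability; no
  calibration layer is provided.
* Importance timelines inherit the variance of per-day AUPRC on modest
  cohorts; ranks for weak features are unstable even when the top
  effectors are clear.
* The expanding-window validation scheme is a declared convention; with
  other temporal split points the internal curves will differ.
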