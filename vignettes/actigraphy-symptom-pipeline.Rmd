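---
title: "Methods: from raw wrist actigraphy to symptom associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw wrist actigraphy to symptom associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, algorithms and design choices behind
`actisym`: what each stage assumes, which parameters matter and why their
defaults were chosen, what the synthetic cohort generator does and does not
emulate, and the numerical conventions used throughout. It states no
empirical result beyond what the package's tests and acceptance script
themselves compute.

## Conventions

All intervals are half-open `[start, end)`. Timestamps are local civil time
without daylight-saving adjustment, stored as UTC `POSIXct` (wearable
device clocks are not timezone-aware). Physical-activity days are anchored
midnight-to-midnight; sleep days noon-to-noon, labeled by the date whose
noon opens the window. Percentiles use the linear-interpolation definition
(`quantile(type = 7)`).

## Ingest

Raw recordings are uniformly sampled tri-axial acceleration (g) with skin
temperature (°C) and ambient light (lux). Calibration applies stored
per-axis offsets and gains (`(value − offset) × gain`); sphere-fit
autocalibration is deliberately out of scope, so a recording must not be
calibrated twice.

Two epoch grids are derived:

* **1-minute grid** — mean ENMO (`max(‖a‖ − 1, 0)`, negatives truncated so
  gravity cancels), ROCAM, per-minute mean light, the low-variation
  statistic, and `T_smooth`, the per-minute mean temperature smoothed by a
  centered 5-minute rolling mean (defined wherever at least one sample
  falls in the window).
* **5-second grid** — the wrist z-angle
  `atan2(a_z, sqrt(a_x² + a_y²)) · 180/π ∈ [−90°, 90°]` computed on
  per-epoch axis medians, which suppresses sub-epoch movement spikes.

**ROCAM convention.** The published ROCAM definition lives in separate
prior work and is not reproduced here; the package adopts the mean absolute
first difference of the acceleration vector magnitude across the samples of
an epoch (units: g per sample interval). The convention is isolated behind
one function (`rocam()`) so it can be swapped, and all thresholds quoted in
these units (notably the non-wear stillness threshold 0.025) are
configurable. The convention is zero for a frozen signal and scales
linearly with fluctuation amplitude, which is all the downstream thresholds
rely on.

## Non-wear detection

A two-pass temperature + movement algorithm on the 1-minute grid.
Candidate minutes satisfy `T_smooth < threshold` **or**
`ΔT_smooth < −0.5 °C/min`.

* **Pass 1 (long removals).** Threshold `T0 = max(26 °C, P5)` where `P5` is
  the 5th percentile of all `T_smooth` values — computed on the smoothed
  minute series, since that is the series the rule thresholds. Maximal
  candidate runs of ≥ 90 min whose run-level ROCAM (mean by default;
  median available) is below 0.025 are non-wear; two runs separated by
  < 15 min are fused, gap included.
* **Pass 2 (15–90 min removals).** Threshold
  `T1 = min(mean_worn − sd_worn, 24 °C)`, where "worn" excludes pass-1
  intervals; if the 5th percentile of *all* readings exceeds `T1`, that
  percentile is used instead; if fewer than 3 full days (4320 min) are worn
  after pass 1, `T1 = 24 °C`. Candidate runs of length `[15, 90)` min
  (a run of exactly 90 min belongs to pass 1) outside pass-1 intervals,
  with run-level ROCAM < 0.025, are kept only when the mean `T_smooth` over
  the first five minutes exceeds that over the last five by ≥ 2 °C — short
  removals show a sharp temperature drop, and the guard rejects
  cool-but-worn sedentary spells. The rule is evaluated on `T_smooth`
  (the raw-vs-smoothed choice is ambiguous in the source method; smoothed
  is consistent with every other clause).

**Known limitation.** The adaptive thresholds assume the recording contains
a non-trivial amount of genuine non-wear. In a warm-wristed, near-fully
worn recording, the 5th-percentile fallback raises `T1` into the worn
temperature range; short-removal candidate runs then end only after
re-warming, and the 2 °C start-vs-end guard rejects them. This is a
property of the algorithm, not of the implementation; the original
analysis backstopped it with visual review. The packaged fixture suite
injects non-wear at realistic adherence levels (~11 % of minutes), where
the thresholds operate in their intended regime.

## Sleep

* **Sustained inactivity.** A 5-s epoch is inactive iff it lies in a
  maximal run where every successive |Δz-angle| < 5°, spanning ≥ 5 min.
  Non-worn epochs are invalid (not wake, not sleep) and break runs.
* **SPT window.** Per noon-to-noon night: inactivity runs ≥ 30 min are
  candidate blocks; blocks separated by < 60 min are fused; the SPT is the
  longest fused block, ties broken toward the block containing 03:00, then
  the earlier block. Finally, inactivity fragments of any length within
  15 min of the window edges are absorbed: a brief posture change a few
  minutes after sleep onset otherwise splits off a sub-30-min fragment and
  systematically delays the detected onset. The 30-min block minimum and
  60-min fusion gap are fixed simplifications of the cited adaptive
  heuristic (bit-parity with that implementation is a non-goal); both are
  arguments of `detect_spt()`. One SPT per night is reported.
* **WASO / efficiency.** `sleep = inactive minutes within SPT`,
  `WASO = SPT − sleep`, `efficiency = sleep / SPT` — the identity
  `WASO + sleep = SPT` holds exactly by construction. Long sedentary spells
  are *conflated* with sleep by design: a 20-h stillness fixture yields a
  20-h detected sleep period, reproducing the known caveat of
  inactivity-based sleep detection.
* **Low variation.** Per-minute statistic: mean over the three axes of the
  mean absolute successive difference within the minute; minutes strictly
  below the threshold, sustained ≥ 5 min, are low-variation. The source
  method chose its threshold by visual inspection and published no number;
  the default (0.01 g) was calibrated on synthetic sleep fixtures and is
  **not** a published value.
* **SRI.** 30-s states are derived from the 5-s inactivity series by
  majority vote (ties and all-invalid epochs are invalid). For the day pair
  (k−1, k), over epochs valid in both days,
  `SRI = 200 · (fraction agreeing) − 100`, stored on day k; missing unless
  the jointly-valid fraction strictly exceeds 0.8. SRI is symmetric in its
  two days and invariant to jointly relabeling sleep/wake.

## Daily features and validity

M10 and L5 are the extreme rolling 10-h / 5-h window means of minute
activity over window starts within the calendar day (no midnight
wrap-around; ties toward the earliest start). Non-worn minutes are excluded
from window means; windows missing more than 25 % of minutes are skipped.
`RA = (M10 − L5)/(M10 + L5)` is scale-invariant. Intensity classification
is lower-inclusive against 40/100/400 mg cut-points (the conventional wrist
defaults; configurable because wrist placement may differ between
participants), with MVPA as plain time above the moderate cut-point — no
bout criterion. The diurnal temperature rhythm is summarized by a
least-squares cosinor `T(t) = mesor + amplitude·cos(2π(t − acrophase)/24)`
fitted to worn minutes (≥ 50 % of the day required); a near-constant input
returns amplitude 0 with missing acrophase. The cosinor triple is this
package's choice of temperature-rhythm summary, standing in for a feature
set whose exact published composition is not specified in the source
analysis.

Validity: activity features require ≥ 75 % wear of the midnight-anchored
day; sleep features ≥ 75 % of the noon-anchored day; SRI additionally its
own > 80 % pair validity. Only complete 24-h windows can be valid, so edge
days of a recording are conservatively invalid.

## PROMs

Diary entries submitted between 17:00 on the associated date and 05:00 the
next morning are "correct"; anytime on the associated or following day is
"feasible"; everything else is dropped (and returned for logging).
De-duplication prefers correct over feasible, then the earliest submission
(the tie rule is not specified by the source; earliest is deterministic and
order-independent). Global pain is the mean of the two pain items (1–10);
global BFI the mean of the nine fatigue items (0–10), missing if any item
is missing. EHP-30 scores are `100 · sum(items) / (4 · n_items)` per
subdomain (11/6/6/4/3 items: pain, control/powerlessness, emotional
wellbeing, social support, self-image) and overall across all 30; by
default any missing item voids the affected scores (a tolerance is
configurable, dropping missing items from both sums).

## Cycle summaries and variability

Per cycle (or participant) and variable: the mean requires ≥ 10 non-missing
daily values; sd, adjusted Fisher–Pearson skewness, IQR, quartiles,
quartile means, TKEO and RMSSD require ≥ 20. (The source text states the
cycle-level mean rule once with an inverted inequality; it is read as a
typo and harmonized with the participant-level rule.) The mean upper/lower
quartile is the mean of the `ceiling(n/4)` largest/smallest values — a
deliberate convention, since the source does not fix the count rule.

Interior gaps of ≤ 3 consecutive missing days are linearly interpolated
before computing `TKEO = (1/N) Σ_{i=2}^{N−1} (x_i² − x_{i−1}x_{i+1})` and
`RMSSD = √((1/N) Σ_{i=1}^{N−1} (x_{i+1} − x_i)²)`; remaining missing values
are removed. Both statistics divide by the series length `N` exactly as
printed in their source definitions, although the sums have `N−2` and `N−1`
terms; `conventional = TRUE` offers the textbook normalization for
comparison. Imputation never alters observed values and never extrapolates.

Adherence covers days 1–28 of each cycle: diary days / 28 and days with
> 75 % wear / 28, with weekly breakdowns; a cycle enters the report only if
more than one diary entry was submitted or any device data was returned;
shorter cycles use the available days as denominator and are flagged.

## Statistics

* **Repeated-measures correlation** follows the ANCOVA formulation: subject
  enters as a factor with a common slope; `r` is the correlation of the
  within-subject centered values carrying the slope's sign,
  `df = n_obs − n_subjects − 1`, p from the F ratio on `(1, df)`. It is
  implemented directly (not by calling a correlation package) so the test
  suite can verify it against an independent explicit `lm()` ANCOVA.
  Subjects with fewer than two complete pairs carry no within-subject
  information and are dropped.
* **Partial correlations** come from the precision matrix
  (`r_ij·rest = −P_ij/√(P_ii P_jj)`, `P = R⁻¹`), Pearson or Spearman
  (ranks first); a singular correlation matrix raises an error naming the
  collinear pair.
* **Symptom mixed models** regress the daily global BFI (or pain) on the
  other symptom score, same-day and previous-day M10, same- and
  previous-night sleep duration and WASO, and SRI, with a participant
  random intercept and continuous-time AR(1) residual correlation indexed
  by enrollment day (`corCAR1`; correlation `φ^Δdays`, which handles
  missing diary days naturally). All variables are z-standardized globally
  over the included complete-case rows (the source specifies
  standardization with no per-subject qualifier). Lags are built within
  participant and cycle, so each cycle's first day drops out of
  complete-case fits — the lag subscripts force this; no lag imputation is
  attempted. Estimation is REML via `nlme::lme`; non-convergence is
  reported as a flagged result, never silently replaced.
* **Cycle-level associations** are Spearman (partial Spearman given
  covariates), flagged "strong" at |R| > 0.3. No multiple-testing
  adjustment is applied, and the output metadata says so — the strength
  flag is descriptive, not inferential.
* **Surgical change.** Each measure is min–max scaled over all daily values
  from all participants jointly; a participant's change is the mean scaled
  value over the 10 days after surgery minus the mean over the pre-surgery
  baseline cycle. Participants with fewer than 3 post-operative points are
  excluded with a reason; the cohort trajectory uses only post-operative
  days covered by at least 50 % of included participants. A constant
  measure has no defined scale and is reported missing. Deltas are
  invariant to affine rescaling of the raw measure.

## The synthetic cohort generator

The generator exists so every stage has ground truth. Defaults encode the
study design the package targets: 28-day smartwatch cycles (up to three),
daily diaries with missingness 0.195 (≈ 80 % diary adherence), a
fatigue–activity coupling of −0.35 (a "strong" negative within-person
association), and 28-day symptom cyclicity.

* **Latent symptoms.** Daily fatigue = phenotype baseline + sinusoid
  (period `symptom_period`) + AR(1) noise, plus exponential flare impulses
  for the flare phenotype and a decaying post-operative bump for the
  post-surgical phenotype. Pain is affine in fatigue plus independent
  noise. Items are ordinal-discretized by rounding and clamping to their
  scales (pain 1–10, BFI 0–10, EHP-30 0–4); EHP-30 severity derives from
  the upper-quartile mean of the cycle's latent pain, reflecting the
  recall-of-worst-symptoms behavior of retrospective questionnaires.
* **Coupling.** The daily activity disturbance is constructed directly as
  `c·fatigue_z + √(1−c²)·z` with iid standard normal `z`, which realizes
  the target within-person correlation `c` analytically — no iterative
  calibration is needed, and recovery is verified end-to-end by the
  acceptance suite through the repeated-measures correlation.
* **Raw signal.** Wake minutes follow a diurnal activity envelope with a
  bout process (active/rest) and orientation jumps; sleep windows
  (23:00 ± jitter to 07:00 ± jitter) are still apart from a few posture
  changes per night; movement is isotropic noise whose magnitude is scaled
  so the minute-mean ENMO tracks the intended daily activity level; a 4-mg
  sensor noise floor is always present.
* **Temperature.** Worn temperature is ~31.5 °C with a realistic spread:
  warmest during sleep (~03:00), coolest mid-afternoon, plus slow drift —
  so the detector's adaptive 5th-percentile thresholds land among cool
  *active* daytime minutes (rejected by the ROCAM test) rather than among
  sleep minutes. Non-wear cools exponentially toward 21 °C ambient with a
  5-min time constant and re-warms with a 3-min constant. A slower cooling
  constant (e.g. 15 min) would leave 15–60-min removals with candidate runs
  shorter than the detector's 15-min floor, because temperature only
  crosses the 24 °C cap ~18 min after removal — the faster constant is also
  the physically plausible choice for a small device leaving skin contact.
* **What is not emulated.** Physiological realism beyond what the detectors
  need: no menstrual-hormone model, no device noise spectra, no
  heteroscedastic diary response styles, no informative (severity-driven)
  missingness by default (an MCAR mechanism is the default), and sleep far
  stiller than real polysomnography-grade behavior. Passing tests therefore
  demonstrate algorithmic correctness and end-to-end recoverability of
  planted effects — not clinical validity on real recordings.

**Problem sizes.** The packaged test and acceptance runs use 1 Hz sampling
(10 Hz is supported), 7–14-day recordings, cohorts of 1–30 participants,
20 seeds for coupling recovery and 50 replicates for mixed-model recovery —
sizes chosen to exercise every code path at desk scale while keeping the
suite quick to run.

## Reproducibility

Every stochastic component derives from a single integer seed:
per-participant seeds are fixed functions of `(cohort seed, participant
index)`, so cohorts are reproducible participant-by-participant and
identical configurations produce byte-identical bundles. `run_pipeline()`
attaches a run manifest (package version, seed, configuration, timestamp)
to every result.
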