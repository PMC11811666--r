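---
title: "Methods: digital phenotyping of insomnia severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital phenotyping of insomnia severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosleep)
```

## What the package models

A digital-phenotyping study of insomnia pairs two views of the same
participants over four weeks: a *subjective* view (questionnaires and a
daily EMA diary) and an *objective* view (a wrist wearable streaming heart
rate every 5 minutes, cumulative step counts, and nightly sleep-stage
estimates). Participants are banded by their Insomnia Severity Index total
(0–7 none, 8–14 mild, 15–21 moderate, 22–28 severe) and every derived
variable is compared across the four bands. The package implements each
stage — scoring, EMA weighting, sleep and circadian feature extraction,
and the comparison workflow — plus a synthetic-cohort generator so the
whole analysis runs without participant data.

## The cosinor model

Heart rate (and, after differencing, step increments) is modeled as a
24-hour cosine,

$$y(t) = M + \beta\cos\left(\tfrac{2\pi t}{24}\right)
            + \gamma\sin\left(\tfrac{2\pi t}{24}\right) + \varepsilon,$$

fit by ordinary least squares in the cos/sin basis — exact for this model
and deterministic, with no nonlinear optimization. The reported
parameters are the MESOR $M$ (rhythm-adjusted mean), amplitude
$A = \sqrt{\beta^2+\gamma^2}$ (peak minus MESOR), acrophase
$\varphi = \operatorname{atan2}(\gamma,\beta)\cdot 24/2\pi$ (peak timing,
hours past midnight in $[0,24)$), and goodness of fit, the coefficient of
determination against the mean-only model, clamped to $[0,1]$.

Participant-level parameters come from sliding 2-day windows advanced by
1 day (27 windows over 28 days): MESOR, amplitude, and goodness of fit
are averaged arithmetically, the acrophase by the circular (vector) mean —
an arithmetic mean would be biased near the midnight wrap, where 23.5 h
and 0.5 h must average to 0 h, not 12 h. The 1-day step is a package
choice; it is configurable. A signed acrophase in $(-12, 12]$ is also
emitted because timing conventions differ across the literature; neither
convention is privileged by the data.

Degenerate inputs follow fixed conventions: a zero-variance window
returns amplitude 0 and goodness of fit 0 with an undefined (`NA`)
acrophase; windows with under 50% epoch coverage are skipped and counted;
fits require at least 3 samples spanning at least (90% of) one period.

## Rest–activity metrics

On hourly-binned step increments (bins with under 50% of their epochs
observed are dropped):

* **Intradaily variability**
  $IV = n\sum_i (x_i-x_{i-1})^2 \big/ \big[(n-1)\sum_i (x_i-\bar x)^2\big]$
  — near 0 for a smooth daily rhythm, about 2 for white noise, above 2
  for fast alternation. With interior missing bins the successive
  differences are restricted to adjacent observed bins and the same
  mean-square normalization is used.
* **Interdaily stability**
  $IS = n\sum_h (\bar x_h-\bar x)^2 \big/ \big[p\sum_i (x_i-\bar x)^2\big]$
  with $p = 24$ hourly classes — 1 for a perfectly repeating daily
  profile, near $1/\text{days}$ for noise.
* **L5 / M10**: the minimum 5-hour and maximum 10-hour moving averages on
  the series' own epoch grid (60 and 120 positions at 5-minute epochs),
  with incomplete trailing windows excluded and onset times reported.
  Windowed sums use per-window summation rather than cumulative-sum
  differencing, so the values match naive window means to full floating
  precision (the test suite holds them to a double-loop oracle at 1e-12).

These hourly-binned definitions are the canonical actigraphy forms; the
package computes them on step increments by default (heart rate is
accepted too). Step streams are cumulative with a midnight reset, so they
are first differenced: the first observed epoch of a day counts from
zero, increments telescope back to the day's final cumulative value, and
a within-day decrease beyond tolerance is a data error naming the epoch.

## Sleep features

Nightly records carry total inactive time, total awake time, stage
minutes (REM, light, deep), and a wake-up count. TST is inactive minus
awake. The sleep-quality percentage is `100·TST/(TST+awake)` — the slept
share of the inactive period. The source material states only that
quality is computed from TST and total awake time and is a percentage;
this ratio is the one formula consistent with both constraints and with
the 80–85% scale such data show, and it is flagged here as a package
decision. By default the percentage is computed from the participant's
mean TST and mean awake time (`quality = "aggregate"`); averaging nightly
percentages is available as `"nightly_mean"` since the two orderings of
mean and ratio are not interchangeable. Nights with zero inactive time
are treated as device non-wear, dropped, and counted.

## EMA weighting

Each daily entry is encoded and weighted by its time-of-day slot:
caffeine, naps, and stress carry weights 1 / 1.5 / 2 for morning /
afternoon / bedtime; alcohol 1.5 / 1 / 2 (morning drinking is rated more
harmful than afternoon drinking). Naps encode 0.5 / 1 / 2 / 3 for the
duration classes under 1 h, 1–2 h, 2–3 h, over 3 h — treated as
half-open intervals $[0,1), [1,2), [2,3), [3,\infty)$ to remove boundary
ambiguity — and stress encodes mild / moderate / severe as 1 / 2 / 3.
The participant-level variable is the sum of weighted daily values over
the study period (days without an entry contribute 0); the period sum is
the default because the reported cohort medians (caffeine around 10–20)
are on a period-aggregate scale, and a per-day mean is exposed as an
option. Multiple same-day entries are summed.

## Instruments and cutoffs

All nine instruments are plain item sums; no reverse scoring is described
for any of them, so none is applied. BRIAN carries 21 items but its total
(range 18–72) sums only the 18 circadian-category items; the 3 chronotype
items are descriptive. STAI-S has no published total range beyond its
20 items at 1–4, hence 20–80. Categorizations: ISI bands as above; IRLS
0–10 / 11–20 / 21–30 / 31–40; PHQ-9 0–4 / 5–9 / 10–19 / 20–27; GAD-7
0–4 / 5–9 / 10–14 / 15–21; AUDIT-C hazardous at ≥ 4 (men) or ≥ 3
(women); SOS-Q high risk *strictly above* 49 — a total of exactly 49 is
assigned to low risk because the cutoff sentence is strict, a boundary
the source leaves unassigned. Screening eligibility (ISI > 15 with ≥ 3
symptom-days/week for the insomnia arm; ISI < 8 with < 3 for the control
arm) is a separate operation from the four-band analysis grouping because
the two serve different purposes and use different boundaries.

## Statistical workflow

Continuous variables pass a per-group Shapiro–Wilk gate at α = 0.05; the
choice of test and level is a package decision (the source names only "a
normality test"), with the rule *any non-normal group ⇒ rank path*.
The rank path runs Kruskal–Wallis plus all 6 pairwise Wilcoxon rank-sum
tests, flagged at the strict Bonferroni threshold 0.05/6 (not the rounded
.0083). The rank-sum test uses the exact null distribution — computed by
subset-sum counting over ranks — for combined samples up to 20 without
ties, and otherwise the normal approximation with mid-ranks,
tie-corrected variance, and continuity correction. The normal path runs
one-way ANOVA with Tukey HSD. Categorical variables use chi-square with a
warning when expected cells fall below 5. No correction is applied across
variables: the Bonferroni family is the 6 pairwise tests within one
variable. "Paired" rank-sum naming in parts of the source is
contradictory for independent groups; the unpaired test is implemented.

Report rows mirror the study-table format: median (IQR) cells on the rank
path, mean (SD) on the ANOVA path, n (%) for categoricals, and an ordered
post hoc narrative built by merging groups that no significant pair
separates and ordering the clusters by location (e.g.
`no_insomnia<mild-to-moderate<severe`); a non-transitive significance
pattern falls back to listing the significant pairs.

## The synthetic cohort

The generator emulates the study conditions, fixed once:

* 250 participants in proportions 0.252 / 0.424 / 0.276 / 0.048
  (largest-remainder apportionment gives exactly 63 / 106 / 69 / 12);
  28 study days from a Monday; heart rate every 5 minutes.
* Heart rate: per-participant true MESOR ~ N(74.56, 7) bpm, amplitude ~
  N(11.0, 2.2) bpm (floored at 0.5), acrophase ~ N(15 h, 1.5 h);
  Gaussian epoch noise with SD 10 bpm, chosen so the cosinor
  goodness of fit lands near the 0.38 such studies report
  ($A^2/2 \,/\, (A^2/2+\sigma^2) \approx 0.38$); clipped to 30–220 bpm;
  2% independent Bernoulli missingness (wear-time compliance is not
  reported in such studies; 2% is a mild default).
* Steps: zero-inflated log-normal epoch increments whose activity
  probability and log-rate both follow an afternoon-peaked cosine,
  accumulated within days — positive, right-skewed, day-active.
* Sleep: one nightly record per study day, identical distributions for
  all groups (TST ~ 375.5 min, awake ~ 65 min, REM/light/deep about 91%
  of TST, wake-ups Poisson 3.7/night) unless the effect profile shifts
  them. Note the arithmetic consequence: mean TST 375.5 and awake 65
  give a quality near 85%, slightly above the 82–83% medians printed in
  comparable tables — group-level medians do not compose, and the
  package keeps the duration centers rather than tuning them.
* Questionnaires: each ISI total is drawn inside its assigned band
  (banding holds in every draw, so analysis grouping recovers the design
  counts exactly); other totals are Gaussian around
  `base + group shift`, rounded, clipped to the legal range, and spread
  over items by constrained sequential allocation that keeps every
  partial sum feasible. Default shifts grade IRLS, DBAS, STAI-S, PHQ-9,
  GAD-7, SOS-Q, and BRIAN by severity (DBAS group means
  65.17 / 81.23 / 94.12 / 119.5) and keep AUDIT-C flat.
* EMA: at most one entry per kind per day, with slot, amount, and
  category distributions per kind. The effect profile acts on the
  log-odds of a daily event, so a zero profile is exactly
  group-invariant; the default grades only stress (daily probability
  about 0.15 / 0.37 / 0.44 / 0.78 across severity), while caffeine,
  alcohol, and naps stay flat — the null results such studies report.

The generator's truth table (assigned group, true circadian parameters)
is returned for recovery tests and diagnostics only; analysis stages
derive groups from the generated ISI items, and the CSV reader never
touches the truth sidecar.

What the generator does *not* emulate: raw accelerometry or the device's
staging heuristics, dropout and attrition, weekday/weekend behavioral
differences, autocorrelated wear gaps, or skewed/heteroskedastic scale
noise. Passing tests therefore certify the pipeline's arithmetic and its
statistical behavior under this stylized data-generating process, not the
device's measurement properties on real participants.

## Problem sizes and verification

The test suite verifies the numerics against independent oracles:
brute-force double loops for IV/IS, enumeration of all window positions
for L5/M10, and full permutation enumeration for exact rank-sum p-values
(combined n ≤ 12), all alongside boundary and invariant properties.
Simulation-based checks use sizes chosen to keep the default run fast
while leaving comfortable statistical margins: 200 replicate cohorts for
the discrepancy pattern (three-standard-error band around the nominal 5%
Type-I error on TST), 200 seeds for amplitude recovery under 5-bpm noise,
and 400 replicates for the omnibus Type-I error. The analysis scripts use
the full default cohort (250 participants, 28 days, about 2 million
heart-rate epochs).

## Known limitations

* The sleep-quality formula and the EMA period-sum aggregation are
  reasoned reconstructions (flagged above), not published equations.
* The acrophase reference convention in published step-rhythm tables is
  unresolved; both conventions are emitted, neither asserted.
* IV/IS are computed from one stream at a time; the package defaults to
  steps and does not attempt multi-stream fusion.
* The Shapiro–Wilk gate at α = 0.05 cannot replicate any specific
  published table's per-row test choices exactly, since those depended on
  an unstated normality procedure.
* No effect sizes, covariate adjustment, or regression modelling: the
  workflow is deliberately the unadjusted group-comparison design.
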