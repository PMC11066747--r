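---
title: "Modeling biobehavioral rhythms and their link to productivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling biobehavioral rhythms and their link to productivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmlink)
```

## The problem

Continuous mobile sensing (smartphone logs, wearables) yields hourly
behavioral feature streams — steps, sleep measures, phone use, audio and
location summaries — over a semester-length study. Such signals cycle:
circadian (24 h) structure dominates, with diurnal (12 h) and nocturnal
(8 h) harmonics. `rhythmlink` quantifies those cycles per participant and
asks whether the *shape and stability* of a person's rhythms track their
weekly self-reported productivity.

## The cosinor model

Within one modeling window, a stream $y(t_i)$ is regressed on a sum of
cosines at fixed candidate periods $T_c \in \{8, 12, 24\}$ hours:

$$y_i = M + \sum_{c=1}^{C} A_c \cos\!\left(\frac{2\pi (t_i - \phi_c)}{T_c}\right) + e_i .$$

Expanding each cosine makes the model linear in $(M, \beta_c, \gamma_c)$
with $\beta_c = A_c\cos(2\pi\phi_c/T_c)$ and
$\gamma_c = A_c\sin(2\pi\phi_c/T_c)$, so it is fit by ordinary least
squares (`stats::lm`). The polar back-transform gives amplitude
$A_c = \sqrt{\beta_c^2+\gamma_c^2}$ and acrophase
$\phi_c = \tfrac{T_c}{2\pi}\,\mathrm{atan2}(\gamma_c,\beta_c) \bmod T_c$.

Assumptions: uncorrelated homoscedastic errors and fixed, known periods.
No autocorrelation correction is applied — with hourly sampling over 2–3
weeks the design is near-orthogonal and the parameter estimates are
unbiased either way, though their nominal SEs would understate
uncertainty for strongly autocorrelated residuals.

Conventions chosen where the field varies:

* **Acrophase** is reported as hours from the reference midnight to the
  component peak, in $[0, T_c)$ — not the negative-radians convention of
  part of the cosinor literature. The two differ by the factor
  $-2\pi/T_c$.
* **Acrophase SE** is in hours (divide by $T_c/2\pi$ for radians). Both
  SEs come from first-order (delta-method) propagation of the coefficient
  covariance through the polar transform; at $A_c = 0$ the phase is
  unidentified and its SE is reported as missing.
* **Percent rhythm (PR)** is the $R^2$ of a *refitted* single-period
  model, not a partition of the full model's sums of squares; the
  integrated PR (IPR) is the $R^2$ of the full multi-period model.
  Because each single-period model is nested in the full one,
  $\mathrm{IPR} \ge \max_c \mathrm{PR}_c$ always.
* **Significance** uses the classical zero-amplitude F test:
  $F = (R^2/2)\,/\,((1-R^2)/(n-3))$ on $(2, n-3)$ df per period, and
  $(2C, n-2C-1)$ df for the full model (IP).
* **Magnitude, orthophase, bathyphase** are read off a 1-minute grid over
  one fundamental period (the LCM of the periods, 24 h here) with
  earliest-time tie-breaking; closed forms exist only for single
  components, and a 1-minute grid locates multi-component extrema to
  better than the reporting resolution.

### Windows

Rhythms are fitted around each survey week $w$ on the hours of weeks
$\max(1, w-1)..\min(16, w+1)$ — 504 hours in the interior, truncated to
336 at the study edges (week 1 and, in a 16-week study, nothing to
truncate at week 15). Truncation rather than shifting keeps the survey
week centered whenever possible.

## Missing data

Field streams lose hours in blocks (sensor dropouts, charging). Per
window and stream:

* fraction < 20% missing → impute; otherwise discard (strict boundary:
  exactly 20% is discarded, matching "less than 20%" retention).
* Imputation is exact linear interpolation between the nearest observed
  anchors, $v_t = v_a + (t-a)(v_b-v_a)/(b-a)$, via `stats::approx`.
  Boundary runs have only one anchor; they are filled with the nearest
  observed value, which adds no artificial trend. Observed values are
  never altered.

## Productivity

Daily self-reports on 0–4 are averaged per survey week over whatever days
were reported (weekdays and weekends; no minimum day count — `n_days` is
recorded for sensitivity checks). A week is *high* iff its mean is ≥ 2,
the scale midpoint. A participant is in the *high* group iff ≥ 2 of the 3
survey weeks are high. Participants missing a survey week are excluded
from grouping and logged, not errored — incomplete response is expected.

## Correlation and aggregation

Step 1 computes, per (feature, rhythm parameter, week) cell across
participants, the Pearson correlation between the parameter and the
weekly mean score, both min–max normalized. Normalization cannot change
$r$ or $p$ (Pearson is affine-invariant — a tested invariant) but keeps
all downstream tables on one scale. Two-tailed $p$ comes from the exact
$t$ transform on $n-2$ df. Cells must have strictly more than 28 complete
pairs; pairs with a missing side (e.g. an undefined acrophase SE) are
dropped cell-wise.

Steps 2–4 combine cells with Fisher's method,
$X = -2\sum \ln p_i \sim \chi^2_{2k}$:

* per feature (over parameters) and per parameter (over features), within
  each week: combined $p$ over all cells; aggregate correlation $C$ =
  mean of the $r$'s of individually significant cells ($p < \alpha$,
  $\alpha = 0.05$), undefined — rendered blank — when none is
  significant;
* across weeks: Fisher over the weekly combined $p$'s and the mean of the
  defined weekly $C$'s;
* the significance score is $S = -\log_{10}(\text{combined } p)$, capped
  at 16 so that heat maps stay on a readable scale.

The concrete aggregation constants (mean-of-significant-$r$, $\alpha$ =
0.05, $S$ as capped $-\log_{10} p$) are this package's definitions; all
four are arguments. Two genuinely open choices are resolved as follows
and kept configurable:

* **Cross-week combination** is hierarchical (Fisher over the weekly
  combined $p$'s), mirroring a cascade whose step 3 consumes step-2
  outputs; `cross_week = "pooled"` instead pools all cell $p$'s of a key
  in one Fisher combination.
* **The $S$ transform**: the Fisher statistic itself grows with the
  number of cells, which would confound "more cells" with "stronger
  evidence"; $-\log_{10}$ of the combined $p$ is comparable across keys
  with different cell counts, hence the default.

Fisher's method assumes independent tests; cells sharing a feature or
week are correlated, so combined $p$'s are anticonservative and should be
read as ranking scores, not calibrated probabilities. This is inherent to
the method, retained deliberately, and flagged here rather than
corrected.

Acrophases are correlated as linear variables on $[0, T)$. That ignores
their circularity: a cohort straddling midnight would split an acrophase
cluster across the interval ends. No circular treatment is applied
(none is standard in this pipeline's design); the generator's default
acrophase ranges keep synthetic cohorts away from the wrap-around, and
real-data users should check theirs.

## The synthetic cohort generator

The generator emulates exactly the statistical structure the analysis
assumes, with a planted, configurable effect:

* **Streams**: per participant and feature, the cosinor generative form
  with participant-specific MESOR, amplitudes and acrophases sampled
  uniformly from group ranges; additive Gaussian hourly noise
  (SD ~ 1 signal unit); *day-level* jitter of phase and amplitude.
  Day-level (not hour-level) jitter is the operative choice: the fitted
  SE parameters measure between-day inconsistency inside a window, so
  rhythm instability must live at the day scale to be visible to them.
* **Missingness**: alternating geometric observed/missing runs with the
  missing-block mean at 1.7 h and overall fraction 0.10 — block-patterned
  like real dropouts, below the discard threshold for most windows.
* **Productivity**: daily score = round-and-clamp of
  $2 + \beta\,s_i + N(0, \sigma_{day})$ with coupling $\beta = 0.8$ and
  $\sigma_{day} = 0.7$, where $s_i$ is the participant's latent stability
  (standardized negative phase jitter). The round-and-clamp form
  reproduces a roughly symmetric score distribution centered near 2
  (the default cohort prints mean ≈ 1.99, median 2) without claiming the
  true response mechanism.
* **Two stability groups** (phase jitter 0.5 h vs 3 h/day, all else
  equal) carry the planted effect: unstable rhythms inflate the fitted
  acrophase SE and deflate percent rhythm, while the coupling lowers
  those participants' scores — so the pipeline should recover a negative
  overall $C$ for the 24-h acrophase SE and a positive one for the 24-h
  percent rhythm. This sign pattern, not any particular magnitude, is
  the tested claim.
* **Seeding**: one global seed expands into per-participant,
  per-stream substreams through a counter-based affine map, so enlarging
  the cohort never perturbs existing participants and every bundle is
  bit-reproducible.

What the generator does **not** emulate: raw sensor events (generation is
at the hourly-feature level), weekday/weekend structure, trends or
non-sinusoidal waveforms, missingness that depends on behavior, ordinal
measurement quirks of the survey, and between-feature correlation beyond
the shared participant profile. Passing tests therefore demonstrate that
the pipeline's inference machinery is correct and calibrated under its
own model assumptions — not that real behavior satisfies those
assumptions.

## Numerical choices and degenerate inputs

* Coefficient covariance is computed from the QR factors of the fit, so
  zero-residual (noiseless) fits return exact zero SEs instead of
  warnings.
* A constant series fits cleanly: amplitudes ≈ 0, all tests
  non-significant, magnitude 0, extrema at the earliest grid point.
* Exact `p = 0` inputs to Fisher's method are clamped to the smallest
  positive double with a warning; combined significance is capped at
  $S = 16$.
* Degenerate correlation cells (constant on either side, or too few
  pairs) are skipped and logged, never silently zeroed.
* Rankings break ties alphabetically so reports are deterministic.

## Problem sizes in the shipped tests

The test suite checks exact recovery and oracle equivalence on
single-window series (336–504 h), SE calibration against 100,000
Monte-Carlo coefficient draws, zero-amplitude type-I error on 10,000
white-noise weeks, nestedness on a 1,000-fit sweep, and planted-effect
sign recovery on twenty 100-participant cohorts run through the entire
pipeline. These sizes make the Monte-Carlo bands tight relative to the
tested tolerances while keeping a full run in minutes on one core.

## Known limitations

* Plain OLS: no weighting, no autocorrelation or heteroscedasticity
  correction.
* Periods are fixed inputs; the package does not estimate free periods or
  population-mean cosinor models across participants.
* Fisher combination over dependent cells (above) — scores rank, they do
  not calibrate.
* Acrophase circularity is ignored in the correlation stage (above).
* The productivity scale is treated as interval-valued when averaged and
  correlated, as is conventional for short ordinal scales.
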