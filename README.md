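# rhythmlink

Biobehavioral rhythms — the daily and sub-daily cycles visible in
passively sensed behavior such as steps, sleep, phone use or location —
can be summarized by a small set of rhythm parameters and related to
outcomes like self-reported productivity. `rhythmlink` implements that
full analysis for cohorts of hourly mobile-sensing feature streams:

1. **Preprocessing** — hourly statistical features from raw events,
   block-missingness profiling, linear interpolation of short gaps, and a
   strict discard rule for streams with ≥ 20% missing hours.
2. **Multi-component cosinor modeling** — per participant, feature and
   survey-week window (the week ± 1 adjacent week), ordinary least squares
   on the linearized model

   y(t) = M + Σ_c A_c · cos(2π(t − φ_c)/T_c) + ε(t)

   with periods T_c ∈ {8, 12, 24} h, yielding MESOR *M*, amplitude *A_c*
   and acrophase *φ_c* per component with delta-method standard errors,
   percent rhythm (PR, the single-period R²), the zero-amplitude F test
   per period, integrated PR and P for the full model, and the magnitude /
   orthophase / bathyphase of the fitted curve over the fundamental
   (24 h) period.
3. **Productivity labeling** — daily 0–4 self-reports averaged per week;
   weeks labeled high iff the mean ≥ 2; participants grouped high iff at
   least 2 of the 3 survey weeks are high.
4. **Correlation and aggregation** — per (feature, rhythm parameter,
   week) cell: min–max normalization, Pearson *r* with a two-tailed *p*,
   and a strict > 28-observation filter; then a Fisher's-method cascade
   that combines cell *p* values per feature and per parameter, averages
   the individually significant *r*'s into an aggregate correlation *C*,
   combines weeks into overall scores *S* = −log10(combined p), and ranks
   the results.

Because raw study data of this kind are private, the package ships a
first-class synthetic-cohort generator: cosinor-generated hourly streams
with participant-specific profiles, day-level phase/amplitude jitter
(rhythm instability), geometric block missingness, and daily productivity
scores coupled to each participant's latent rhythm stability. This gives
every stage a ground truth for parameter-recovery and planted-effect
tests.

## Worked example

Simulate one noisy stream with 24-h and 12-h components and refit it:

```r
library(rhythmlink)

prof <- rhythm_profile(mesor = 10, amplitudes = c("24" = 2, "12" = 1),
                       acrophases = c("24" = 14, "12" = 3), noise_sd = 1)
stream <- simulate_feature_stream(prof, n_hours = 504, seed = 42)
fit <- fit_cosinor(stream, periods = c(8, 12, 24))
tidy(fit)
#> # A tibble: 3 × 7
#>   period amplitude amp_se acrophase phi_se      pr  p_value
#>    <dbl>     <dbl>  <dbl>     <dbl>  <dbl>   <dbl>    <dbl>
#> 1      8     0.122 0.0611      4.72  0.638 0.00218 5.78e- 1
#> 2     12     0.933 0.0611      3.05  0.125 0.128   1.35e-15
#> 3     24     2.02  0.0611     13.9   0.116 0.597   1.01e-99
glance(fit)
#> # A tibble: 1 × 9
#>   mesor mesor_se   ipr        ip magnitude orthophase bathyphase …
#> 1  9.97   0.0432 0.727 8.85e-137      2.44       14.4       23.2 …
```

The generating parameters (MESOR 10, A₂₄ = 2 at φ₂₄ = 14 h, A₁₂ = 1 at
φ₁₂ = 3 h) are recovered within their standard errors; the absent 8-h
component is correctly non-significant (p = 0.58), and the spurious 8-h
amplitude is within ~2 SE of zero.

A full cohort analysis is one call:

```r
res <- run_pipeline(pipeline_config(
  simulation = simulation_config(n_participants = 100, seed = 1),
  seed = 1
))
res                      # stage-by-stage row counts
res$scores$overall       # aggregate C and S per feature / parameter
plot_score_heatmap(res$scores$weekly, value = "C")
```

On the default cohort — two stability groups whose day-to-day phase
jitter is 0.5 h vs 3 h, with productivity coupled to stability — the
overall aggregate correlation is strongly negative for the 24-h acrophase
SE (unstable rhythms, lower productivity) and strongly positive for the
24-h percent rhythm (clean rhythms, higher productivity).

The same pipeline runs from a shell via
`Rscript inst/scripts/rhythmlink.R --out run_dir --seed 1`, writing every
stage's CSV plus a manifest with row counts and checksums.

## Documentation

The methods vignette (`vignettes/rhythm-productivity-pipeline.Rmd`)
describes the model, every tunable constant, what the synthetic generator
does and does not emulate, and the package's numerical conventions.
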