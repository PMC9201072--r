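# gaitlong

Longitudinal modelling of three-dimensional gait analysis (3DGA) features
in progressive neuromuscular disease, built around the natural history of
gait in ambulant boys with Duchenne muscular dystrophy (DMD).

Cohorts in rare disease are *mixed cross-sectional longitudinal*:
children enrol at different baseline ages and are re-measured a variable
number of times at irregular intervals.  `gaitlong` provides the whole
pipeline for such data, for gait labs and biostatisticians:

* **Waveforms and features** — long-format per-cycle kinematic/kinetic
  waveform tables in; resampling to the canonical 101-point gait-cycle
  grid (shape-preserving Hermite interpolation); per-session cycle
  averaging; extraction of the 31 predefined gait features
  (4 spatiotemporal with Hof dimensionless normalisation,
  17 kinematic including the Gait Profile Score, 10 kinetic), each on
  its phase window (stance, swing, loading response, push-off, initial
  contact), one analysed side per child.
* **Cross-sectional comparison** — patient baseline vs
  typically-developing reference: median (Q1–Q3) descriptives,
  Mann–Whitney U tests, stepwise Benjamini–Hochberg FDR control across
  the comparison family.
* **Longitudinal engine** — a purpose-built REML fitter for the marginal
  linear mixed model

  ```
  y_ij = b0 + b1·t + b2·t² + b3·a + b4·a² + b5·a³ + b6·t·a
         + u_1i + u_2i·t + e1_ij + e2_ij
  ```

  with time-in-study `t` (longitudinal effect), centred baseline age `a`
  (cross-sectional effect), random intercept/slope `u`, measurement
  error `e1`, and optional Gaussian/exponential serial correlation `e2`;
  plus semi-variogram diagnostics, the boundary mixture-χ²₁:₂ likelihood
  ratio test for the random slope, sandwich-robust Wald F inference,
  empirical Bayes outlier screening, and the five-step model-building
  workflow tying them together.
* **Synthetic cohorts** — a generator reproducing the study conditions
  (27 subjects, baseline ages 4.6–15 y, 2–9 visits at 5–35-month gaps)
  under published per-feature fixed effects, and a waveform-level
  session generator whose curves hit requested feature targets exactly,
  so everything is testable without clinical data.

## Worked example

```r
library(gaitlong)

# 1. a synthetic session -> the 31-entry feature vector
ref <- synthetic_reference_bands()
ses <- simulate_session_waveforms(
  targets = c(max_ant_pelvic_tilt = 16.36, dorsiflex_ic = 0.80),
  seed = 1, subject = "D01", weaker_side = "left"
)
feats <- session_features(ses, ref)
round(feats[c("max_ant_pelvic_tilt", "dorsiflex_ic", "gps", "wv_norm")], 3)
#>   max_ant_pelvic_tilt dorsiflex_ic   gps wv_norm
#> 1               16.36          0.8 4.211   0.402

# 2. the five-step longitudinal workflow on a simulated cadence cohort
truth <- default_truth_sets()$cadence
cohort <- simulate_cohort(cohort_design(), truth, seed = 1)
reports <- run_longitudinal_analysis(
  list(cadence = cohort),
  workflow_config(fit_options = list(n_restarts = 1))
)
print(reports$cadence)
#> Workflow report for 'cadence'
#>   preliminary fixed: time, time2, age, age2, age3, time_age
#>   preliminary random: intercept_slope
#>   serial: none
#>   final random: intercept_slope
#>   final fixed: time, age
#>   outliers flagged: none
render_fixed_effects_table(reports)
#>   response status (Intercept)    time time2     age age2 age3 time_age
#> 1  cadence     ok      2.896* -0.088*       -0.117*
```

The extracted pelvic tilt and dorsiflexion values reproduce the requested
targets exactly (the session generator's round-trip contract); the GPS of
4.2° is this synthetic session's RMS kinematic deviation from the
synthetic reference bands.  The workflow report shows the backward
elimination landing on a model with a longitudinal cadence decline
(−0.088 steps/s per year on this particular simulated cohort; the
generating value is −0.058) and a cross-sectional baseline-age decline,
both starred at p < 0.05 by robust Wald F tests.

Real data enter through `read_cycles()` (cycle/event/session CSV tables),
`extract_gait_features()`, `longitudinal_datasets()`, and
`compare_groups()`; see the function documentation and the methods
vignette (`vignettes/longitudinal-gait-modelling.Rmd`) for the model,
its assumptions, and every tunable default.

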