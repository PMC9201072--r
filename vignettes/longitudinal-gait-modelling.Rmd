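---
title: "Modelling the longitudinal evolution of gait features in Duchenne muscular dystrophy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the longitudinal evolution of gait features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitlong)
```

## The problem

Duchenne muscular dystrophy (DMD) causes progressive muscle weakness, and
the gait pattern of ambulant boys deteriorates in characteristic ways:
increasing anterior pelvic tilt, loss of hip extension, a widening base of
support, a progressive drop foot, and weakening push-off.  Instrumented 3D
gait analysis (3DGA) quantifies this as joint kinematic waveforms (degrees)
and bodyweight-normalised kinetic waveforms (Nm/kg, W/kg) over the gait
cycle, summarised into discrete features (minima, maxima, ranges of motion,
values at gait events) plus spatiotemporal parameters and the Gait Profile
Score (GPS).

Natural-history cohorts in rare disease are necessarily *mixed
cross-sectional longitudinal*: children enrol at different ages (the
cross-sectional axis) and are then re-measured a variable number of times
at irregular intervals (the longitudinal axis).  `gaitlong` implements the
full analysis pipeline for such data: waveform ingestion and feature
extraction, a cross-sectional baseline comparison against
typically-developing (TD) children, and — the core of the package — a
restricted maximum likelihood (REML) engine for the marginal linear mixed
model that separates within-child change from between-child age effects.

## The model

For a gait feature $y_{ij}$ of child $i$ at visit $j$,

$$
y_{ij} = \beta_0 + \beta_1 t_{ij} + \beta_2 t_{ij}^2
       + \beta_3 a_i + \beta_4 a_i^2 + \beta_5 a_i^3
       + \beta_6\, t_{ij} a_i
       + b_{1i} + b_{2i} t_{ij} + \varepsilon^{(1)}_{ij}
       + \varepsilon^{(2)}_{ij},
$$

where $t_{ij}$ is time in years since the child's first included session
and $a_i$ is the baseline age minus the cohort minimum, so $\beta_0$ is
the expected response of the youngest entrant at study entry.  The
polynomial time terms carry the *longitudinal* effect, the baseline-age
terms the *cross-sectional* effect, and $\beta_6$ lets the rate of change
depend on entry age.  $(b_{1i}, b_{2i})^\top \sim N(0, G)$ are a random
intercept and slope, $\varepsilon^{(1)}$ is iid measurement error with
variance $\sigma^2$, and $\varepsilon^{(2)}$ is an optional stationary
serial-correlation process with variance $\tau^2$ and correlation
$\exp(-u/\phi)$ (exponential) or $\exp(-(u/\phi)^2)$ (Gaussian) at
within-child lag $u$.  Marginally,
$V_i = Z_i G Z_i^\top + \sigma^2 I + \tau^2 H_i(\phi)$.

### Estimation

`reml_fit()` maximises the restricted likelihood, profiled analytically
over the fixed effects (GLS) *and* over $\sigma^2$, so the numerical
search runs only over variance ratios: the Cholesky factor of
$G/\sigma^2$ and, when present, $(\tau^2/\sigma^2, \phi)$ on the log
scale.  The serial-free path uses Woodbury identities on per-subject
cross-products, which makes a 27-subject fit take on the order of 0.1 s.
Searches start from a moment-based estimate (OLS residual variance split
into between- and within-subject parts) plus seeded random restarts
(default 5); variance components are allowed to collapse to the boundary
(log-parameterisation reaches it as $-\infty$; in practice $\hat G$
reaches $10^{-12}$-scale values there).  Non-convergence on all starts is
an error carrying diagnostics, never a silent result.  On serial-free
models the engine reproduces `nlme::lme` fixed effects to $10^{-4}$
relative and the REML log-likelihood to $10^{-6}$ (tested).

### Inference

Fixed effects are tested with Wald F statistics built on the sandwich
(robust) covariance $A^{-1} B A^{-1}$, guarding against covariance
misspecification.  The denominator degrees of freedom are
`n_subjects - p` (a between–within convention; the reference analysis
software's choice is not published, so this is explicit and
configurable).  The random slope is tested with the boundary likelihood
ratio test against the equal-weight $\chi^2_{1:2}$ mixture.  Subject-level
random effects are predicted by empirical Bayes and screened for outliers
via the Mahalanobis distance of the prediction at a configurable
$\chi^2$ quantile (default 0.99); flags are advisory, and removal (with a
full workflow re-run) is opt-in.

## The model-building workflow

`run_longitudinal_analysis()` mechanises the five-step procedure per
feature:

1. **Mean structure** — loess smooths (span 0.75) of the response against
   time and against baseline age; the lowest polynomial degree (time
   $\le 2$, baseline age $\le 3$) whose least-squares fit reproduces the
   smooth within 2% RMS of the smooth's range is kept, with the
   time-by-baseline-age interaction always included a priori.  A smooth
   whose whole range is below the loess residual SD contributes degree 0.
   The original procedure relied on visual inspection; these two
   tolerances replace the eye and are exposed in `workflow_config()`.
   The 2% value was chosen because loess attenuates the extremes of
   higher-order trends: at 5% a genuinely cubic baseline-age trend is
   regularly mistaken for a quadratic.
2. **Random structure** — squared OLS residuals regressed on time; a
   significantly increasing variance function (5%) selects
   intercept+slope, otherwise intercept only.
3. **Serial structure** — REML fits without serial correlation, with
   Gaussian, and with exponential serial correlation.  Between Gaussian
   and exponential the higher restricted likelihood wins; the winner is
   retained over "none" only when it improves AIC (two extra
   parameters).  This is a deliberate information-criterion reading of
   the likelihood comparison, since the richer structure can never lose
   on likelihood alone.  The semi-variogram (`semivariogram()`) is
   produced as a diagnostic for random-intercept candidates.
4. **Random-effect reduction** — the slope is dropped when the
   $\chi^2_{1:2}$ mixture LRT is non-significant at 5%.
5. **Fixed-effect reduction** — backward elimination with robust Wald F
   tests at 5%, no multiplicity correction (the longitudinal aim is
   explorative), respecting the polynomial hierarchy: a main effect only
   becomes removable once its higher-order terms and the interaction are
   gone.  The elimination order (least significant removable term first)
   and single-path backward search are conventions; the source analysis
   does not state its order.

## Feature extraction choices

* Waveforms live on the canonical 101-point grid (0–100% of the gait
  cycle); non-canonical grids are resampled with shape-preserving cubic
  Hermite interpolation (Fritsch–Butland slopes, zeroed at local
  extrema).  Shape preservation matters because windowed minima/maxima
  are the features: an interpolant that overshoots at a curve's extremum
  (as unconstrained splines, and even `splinefun`'s `"monoH.FC"` on
  non-monotone data, do) would bias them.
* Phase windows are defined on the grid: stance = points at or before
  foot-off, swing = points after it, loading response = 0–12%, push-off =
  40%–foot-off.  The percentage bounds for LR/PO follow standard gait
  terminology (they are not published for the original custom software)
  and are overridable via `phase_windows()`.
* Sides are never pooled.  The analysed side is the clinically weaker
  side when recorded, otherwise a seeded uniform draw
  (`select_analysis_side()`).
* The GPS uses the nine per-side kinematic variables (pelvis ×3, hip ×3,
  knee flexion, ankle dorsiflexion, foot progression).  Whether the
  original index used 9, 12, or 15 variable scores is not stated; the
  9-variable per-side convention is adopted here since one side per child
  is analysed.  Reference bands are supplied as data
  (`read_reference_bands()`); `synthetic_reference_bands()` ships a
  synthetic TD stand-in for testing and examples, not a clinical
  reference.
* Sign conventions: anterior pelvic tilt, hip/knee flexion, hip
  adduction, ankle dorsiflexion, internal foot progression, and internal
  extensor/plantar-flexor moments are positive.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions: 27 subjects, baseline
ages uniform on 4.6–15 years, 2–9 visits at uniform 5–35-month gaps,
follow-up truncated at 5 years.  `default_truth_sets()` transcribes the
published per-feature fixed effects (30 features; the minimum hip
extension moment has no published longitudinal fit) as generative truths.
Variance components were not published, so the defaults are explicit
assumptions scaled to each feature's published baseline spread: with
$s = \max(|\mathrm{median}|, \mathrm{IQR})$, the random-intercept SD is
$0.15s$, the slope SD a third of that, the residual SD $0.10s$, serial
correlation off.  The IQR enters the scale because several kinetic
features have medians near zero, where a median-only rule would produce
degenerate (or, with a fixed absolute floor, absurdly large) noise; every
truth object carries an "assumed" provenance note.  Features are
simulated independently — real gait features are biomechanically coupled,
so passing recovery tests says nothing about cross-feature structure.

`simulate_session_waveforms()` generates waveform-level sessions whose
windowed extrema hit requested feature targets: each variable's mean
curve interpolates control points placed on the grid (monotone segments
cannot overshoot, so the windowed extremum *is* the control value), and
per-cycle deviations are smooth sinusoids whose amplitudes are centred
across cycles, making the cycle average reproduce the targets exactly
while individual cycles vary.  Within-curve consistency is enforced
(e.g., stance knee ROM must equal stance max − min; full-cycle hip ROM
cannot be smaller than swing max − stance min), and jointly infeasible
targets are refused rather than silently adjusted.

## What the tests do and do not show

The acceptance-style simulations regenerate cohorts under the published
coefficients and verify that the engine's mean estimates recover them;
problem sizes are 200 cohorts of 27 subjects per feature for the headline
recovery runs, and 60–200 replicates at 15–60 subjects for the property
suites (level of the boundary LRT, FDR control at 36 comparisons,
sandwich/model-based agreement, EB outlier detection).  They validate the
*estimator* under the *assumed* generative conditions; they cannot
validate the unpublished variance components, the manual cycle-quality
screening of real 3DGA data, or biomechanical coupling across features.

## Known limitations

* Gaussian vs exponential serial correlation is only weakly identifiable
  at cohort scale: with a free measurement-error nugget the two families
  fit each other's data with restricted log-likelihood gaps of a few
  units at most (verified against `nlme`), so step 3's form choice is
  reported but should not be over-interpreted.  Detection of serial
  correlation *per se* is well powered.
* The robust-F denominator df and the elimination order in step 5 are
  conventions (configurable), not reproductions of unpublished choices.
* Kenward–Roger or containment df are not implemented.
* Crossed random effects, Bayesian fitting, and per-age-group residual
  variances are out of scope, as are C3D parsing, marker-level
  processing, and event autodetection (inputs are long-format per-cycle
  tables with event annotations).
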