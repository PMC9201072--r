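Package: gaitlong
Title: Longitudinal Modelling of Three-Dimensional Gait Features in
    Duchenne Muscular Dystrophy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mixed cross-sectional longitudinal analysis of
    three-dimensional gait analysis data in progressive neuromuscular
    disease.  Reads per-cycle joint kinematic and kinetic waveforms,
    resamples them to the 101-point gait-cycle grid, and extracts a
    predefined set of 31 spatiotemporal, kinematic, and kinetic gait
    features including Hof dimensionless normalisation and the Gait
    Profile Score.  Cross-sectional group comparisons use Mann-Whitney U
    tests with stepwise Benjamini-Hochberg false-discovery-rate control.
    Longitudinal trajectories are modelled with a purpose-built restricted
    maximum likelihood (REML) engine for linear mixed models with
    polynomial time and baseline-age fixed effects, random intercepts and
    slopes, measurement error, and optional Gaussian or exponential serial
    correlation, together with semi-variogram diagnostics, boundary
    (mixture chi-square) likelihood ratio tests, sandwich-robust Wald F
    inference, and empirical Bayes outlier screening.  A five-step
    model-building workflow and a synthetic cohort simulator make the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite
Config/testthat/edition: 3
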