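# Synthetic longitudinal cohorts generated under the marginal mixed
# model, with default fixed-effect truth sets taken from the published
# per-feature model fits.  Variance components were not published; the
# defaults here are explicit assumptions scaled to each feature's
# reported baseline spread (see the truth-set metadata).

#' Cohort sampling design
#'
#' Defaults emulate the study cohort: 27 boys entering at baseline ages
#' 4.6-15 years, measured 2-9 times at 5-35-month intervals, with
#' follow-up truncated at 5 years.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param age_range Baseline-age range (years), sampled uniformly.
#' @param visits_range Integer range of visits per subject, uniform.
#' @param gap_months Inter-visit gap range (months), uniform.
#' @param max_followup_years Visits beyond this horizon are dropped
#'   (at least the first two visits are always kept).
#' @return List of class `"cohort_design"`.
#' @export
cohort_design <- function(n_subjects = 27L, age_range = c(4.6, 15),
                          visits_range = c(2L, 9L),
                          gap_months = c(5, 35),
                          max_followup_years = 5) {
  if (n_subjects < 2L) stop_data("need at least 2 subjects")
  if (any(gap_months <= 0)) stop_data("visit gaps must be positive")
  structure(
    list(n_subjects = as.integer(n_subjects), age_range = age_range,
         visits_range = as.integer(visits_range),
         gap_months = gap_months,
         max_followup_years = max_followup_years),
    class = "cohort_design"
  )
}

truth_beta_names <- c("(Intercept)", LMM_TERMS)

validate_truth <- function(truth) {
  stopifnot(
    is.list(truth), all(truth_beta_names %in% names(truth$beta)),
    truth$sigma2 >= 0, all(eigen(truth$G)$values >= -1e-12),
    truth$serial %in% c("none", "gaussian", "exponential"),
    truth$tau2 >= 0, truth$serial == "none" || truth$phi > 0
  )
  invisible(truth)
}

make_truth <- function(id, beta, scale, serial = "none", tau2_frac = 0,
                       phi = 1) {
  b <- setNames(numeric(length(truth_beta_names)), truth_beta_names)
  b[names(beta)] <- beta
  sd_int <- 0.15 * scale
  sd_slope <- sd_int / 3
  sd_resid <- 0.10 * scale
  tau2 <- tau2_frac * sd_resid^2
  list(
    response = id,
    beta = b,
    fixed_terms = setdiff(names(beta), "(Intercept)"),
    G = diag(c(sd_int^2, sd_slope^2)),
    sigma2 = sd_resid^2,
    serial = serial, tau2 = tau2, phi = phi,
    variance_provenance = paste(
      "assumed: intercept SD = 15% and residual SD = 10% of the",
      "feature's reported baseline scale (max of |median|, IQR);",
      "slope SD = intercept SD / 3; serial off unless stated"
    )
  )
}

#' Default longitudinal truth sets
#'
#' One generative parameter set per gait feature, with fixed effects
#' transcribed from the published per-feature mixed-model fits (all
#' printed terms included, significant or not; absent terms are zero).
#' Variance components were not published and are package assumptions
#' scaled to each feature's reported baseline median/IQR; every truth
#' carries that provenance note.  The feature "Min hip ext mom stance"
#' has no published longitudinal fit, so 30 truth sets are returned.
#'
#' @return Named list of truth sets (see [simulate_cohort()]).
#' @export
default_truth_sets <- function() {
  reg <- gait_feature_registry()
  sc <- setNames(pmax(abs(reg$ref_median), reg$ref_q3 - reg$ref_q1),
                 reg$id)
  B <- function(...) c(...)
  spec <- list(
    cadence = B("(Intercept)" = 2.617, time = -0.058, age = -0.124,
                age2 = 0.006),
    wv_norm = B("(Intercept)" = 0.457, time = -0.012, age = -0.011),
    sl_norm = B("(Intercept)" = 0.785, time = -0.016, age = -0.009),
    sw_norm = B("(Intercept)" = 0.262, time = -0.027, time2 = 0.005,
                age = 0.003, time_age = 0.005),
    gps = B("(Intercept)" = 6.69, time = 0.19, age = -0.57, age2 = 0.09,
            time_age = 0.10),
    max_ant_pelvic_tilt = B("(Intercept)" = 15.71, time = 1.33,
                            age = -1.42, age2 = 0.26),
    rom_pelvic_obliquity = B("(Intercept)" = 7.60, time = 0.58,
                             age = 0.74),
    rom_pelvic_rotation = B("(Intercept)" = 13.32, time = 1.35,
                            age = -1.27, age2 = 0.25),
    min_hip_flex_stance = B("(Intercept)" = -7.63, time = 1.88,
                            age = -0.22, age2 = 0.23),
    max_hip_flex_swing = B("(Intercept)" = 37.10, time = -0.22,
                           age = 1.08, time_age = 0.30),
    rom_hip_sagittal = B("(Intercept)" = 47.10, time = -0.60,
                         age = -0.76),
    max_hip_ext_mom_stance = B("(Intercept)" = 0.502, time = 0.035,
                               time2 = -0.020, age = 0.065,
                               age2 = -0.010),
    max_hip_power_stance = B("(Intercept)" = 0.475, time = 0.066,
                             time2 = -0.030, age = 0.061, age2 = -0.008),
    min_hip_add_stance = B("(Intercept)" = -3.32, time = -0.42,
                           age = -1.24, age2 = 0.094),
    min_hip_add_swing = B("(Intercept)" = -6.92, time = -0.48,
                          age = -1.42, age2 = 0.12),
    max_hip_abd_mom_stance = B("(Intercept)" = 0.537, time = 0.029,
                               age = 0.017, time_age = -0.010),
    max_knee_flex_stance = B("(Intercept)" = 32.14, time = -0.85,
                             age = 0.73),
    min_knee_flex_stance = B("(Intercept)" = 3.73, time = -0.49,
                             age = 1.00),
    rom_knee_sagittal_stance = B("(Intercept)" = 26.06, time = 0.61,
                                 time2 = -0.36, age = 1.03,
                                 age2 = -0.12),
    max_knee_flex_swing = B("(Intercept)" = 68.83, time = -1.25),
    max_knee_ext_mom_stance = B("(Intercept)" = 0.418, time = -0.018),
    min_knee_ext_mom_stance = B("(Intercept)" = -0.043, time = -0.017,
                                time2 = 0.008, age = -0.068,
                                age2 = 0.020, age3 = -0.001),
    dorsiflex_ic = B("(Intercept)" = 1.70, time = -1.20, age = 0.52,
                     age2 = -0.15),
    max_dorsiflex_stance = B("(Intercept)" = 11.34, time = -0.59,
                             age = 2.64, age2 = -0.32),
    max_dorsiflex_swing = B("(Intercept)" = 2.14, time = 0.06,
                            age = 2.09, age2 = -0.29, time_age = -0.35),
    min_plantarflex_mom_lr = B("(Intercept)" = -0.060, time = 0.010),
    max_plantarflex_mom_po = B("(Intercept)" = 0.867, time = -0.009,
                               age = 0.037),
    min_ankle_power_lr = B("(Intercept)" = -0.533, time = -0.026,
                           age = 0.059, age2 = -0.011),
    max_ankle_power_po = B("(Intercept)" = 2.875, time = -0.026),
    max_foot_prog_stance = B("(Intercept)" = -6.29, time = 2.10,
                             age = -3.06, age2 = 0.40)
  )
  out <- lapply(names(spec), function(id) {
    validate_truth(make_truth(id, spec[[id]], sc[[id]]))
  })
  names(out) <- names(spec)
  out
}

#' Simulate one longitudinal cohort under the mixed model
#'
#' Draws baseline ages and visit schedules from the design, then
#' generates responses as the fixed-effect mean surface (with baseline
#' age centred at the design minimum) plus subject random effects drawn
#' from `N(0, G)`, an optional serial Gaussian process with covariance
#' `tau2 H(phi)`, and iid measurement error `N(0, sigma2)`.
#'
#' @param design A [cohort_design()].
#' @param truth A truth set (see [default_truth_sets()]).
#' @param seed Integer seed; the draw is fully reproducible.
#' @return An [lmm_data()] with `center_age` fixed at the design's
#'   minimum baseline age.
#' @export
simulate_cohort <- function(design, truth, seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  validate_truth(truth)
  with_seed(seed, {
    G <- as.matrix(truth$G)
    # exact zeros in G must stay exact (noise-free limit)
    cG <- if (all(G == 0)) G else
      chol(G + diag(1e-10 * max(diag(G)), nrow(G)))
    subj <- sprintf("S%02d", seq_len(design$n_subjects))
    rows <- lapply(seq_len(design$n_subjects), function(i) {
      ba <- runif(1, design$age_range[1L], design$age_range[2L])
      nv_choices <- seq(design$visits_range[1L], design$visits_range[2L])
      nv <- nv_choices[sample.int(length(nv_choices), 1L)]
      gaps <- runif(nv - 1L, design$gap_months[1L],
                    design$gap_months[2L]) / 12
      times <- c(0, cumsum(gaps))
      keep <- times <= design$max_followup_years
      keep[seq_len(min(2L, length(times)))] <- TRUE  # always >= 2 visits
      times <- times[keep]
      b <- drop(t(cG) %*% rnorm(nrow(G)))
      n_i <- length(times)
      age <- ba - design$age_range[1L]
      mean_i <- truth$beta[["(Intercept)"]] +
        truth$beta[["time"]] * times + truth$beta[["time2"]] * times^2 +
        truth$beta[["age"]] * age + truth$beta[["age2"]] * age^2 +
        truth$beta[["age3"]] * age^3 +
        truth$beta[["time_age"]] * times * age
      Zb <- b[1L] + if (nrow(G) == 2L) b[2L] * times else 0
      serial <- numeric(n_i)
      if (truth$serial != "none" && truth$tau2 > 0) {
        U <- abs(outer(times, times, "-"))
        H <- truth$tau2 * serial_correlation(U, truth$serial, truth$phi)
        serial <- drop(t(chol(H + diag(1e-10, n_i))) %*% rnorm(n_i))
      }
      eps <- rnorm(n_i, sd = sqrt(truth$sigma2))
      data.frame(subject = subj[i], time = times, baseline_age = ba,
                 value = mean_i + Zb + serial + eps,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    lmm_data(df$subject, df$time, df$baseline_age, df$value,
             response = truth$response,
             center_age = design$age_range[1L])
  })
}

#' Generating model specification of a truth set
#'
#' The [lmm_spec()] whose fixed terms are exactly the truth's active
#' terms, with the truth's random and serial structure — the spec under
#' which [reml_fit()] is consistent for the truth's parameters.
#'
#' @param truth A truth set.
#' @return An [lmm_spec()].
#' @export
truth_spec <- function(truth) {
  lmm_spec(fixed = truth$fixed_terms,
           random = if (nrow(as.matrix(truth$G)) == 2L) {
             "intercept_slope"
           } else "intercept",
           serial = truth$serial)
}

#' Parameter-recovery protocol for a truth set
#'
#' Simulates `length(seeds)` cohorts under the truth, refits each by
#' REML with the generating term set, and summarises the fixed-effect
#' estimates: their mean and Monte-Carlo standard error of the mean.
#'
#' @param truth A truth set (see [default_truth_sets()]).
#' @param seeds Integer vector of cohort seeds (one cohort per seed).
#' @param design A [cohort_design()].
#' @param fit_options Options passed to [reml_fit()].
#' @return List with `estimates` (matrix, one row per cohort), `mean`,
#'   and `mc_se` (named by coefficient).
#' @export
simulate_recovery <- function(truth, seeds = 1:200,
                              design = cohort_design(),
                              fit_options = list(n_restarts = 1L)) {
  spec <- truth_spec(truth)
  k <- 1L + length(truth$fixed_terms)
  est <- t(vapply(seeds, function(s) {
    d <- simulate_cohort(design, truth, seed = s)
    reml_fit(d, spec, options = fit_options)$beta
  }, numeric(k)))
  list(estimates = est, mean = colMeans(est),
       mc_se = apply(est, 2, sd) / sqrt(nrow(est)))
}
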