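# Shared fixture builders; everything is generated in code.

with_seed <- gaitlong:::with_seed

# A session whose nine kinematic waveforms (plus optional kinetics) are
# given directly, with `n` identical cycles each.
session_from_waves <- function(waves = list(), foot_off = 60,
                               sides = "left", n = 1L,
                               weaker_side = "unknown", ...) {
  defaults <- setNames(
    rep(list(rep(0, 101)), length(gait_variables()$kinematic)),
    gait_variables()$kinematic
  )
  defaults[names(waves)] <- waves
  cycles <- list()
  for (sd_ in sides) {
    for (v in names(defaults)) {
      for (k in seq_len(n)) {
        cycles[[length(cycles) + 1L]] <-
          gait_cycle(v, sd_, defaults[[v]], foot_off)
      }
    }
  }
  gait_session("S1", "1", cycles, age_years = 8, leg_length_m = 0.6,
               weight_kg = 25,
               spatiotemporal = list(cadence = 2.2,
                                     walking_velocity = 1.0,
                                     step_length = 0.5,
                                     step_width = 0.15),
               weaker_side = weaker_side, ...)
}

# Custom generative truth for simulate_cohort.
toy_truth <- function(beta, sd_int = 1, sd_slope = 0.3, sd_resid = 0.5,
                      serial = "none", tau2 = 0, phi = 1,
                      response = "toy") {
  b <- setNames(numeric(7),
                c("(Intercept)", "time", "time2", "age", "age2", "age3",
                  "time_age"))
  b[names(beta)] <- beta
  list(response = response, beta = b,
       fixed_terms = setdiff(names(beta), "(Intercept)"),
       G = diag(c(sd_int^2, sd_slope^2)), sigma2 = sd_resid^2,
       serial = serial, tau2 = tau2, phi = phi)
}

# Small cohorts keep the simulation-heavy tests fast.
small_design <- function(n_subjects = 15L) {
  cohort_design(n_subjects = n_subjects, visits_range = c(3L, 5L),
                gap_months = c(8, 16))
}

fast_opts <- list(n_restarts = 1L)

# Flat reference bands (all-zero), matching session_from_waves defaults.
zero_reference <- function() {
  do.call(rbind, lapply(gait_variables()$gps, function(v) {
    data.frame(variable = v, percent = 0:100, value = 0)
  }))
}
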