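# Waveform-level session generator: smooth parametric gait curves whose
# phase-windowed extrema hit requested discrete-feature targets exactly,
# wrapped in multiple per-cycle realisations.
#
# Each variable's mean curve is a monotone-cubic interpolant through
# control points placed on the integer % grid, with the targeted feature
# values AT the control points; monotone interpolation never overshoots,
# so the windowed extremum of the mean curve equals the control value.
# Per-cycle deviations are smooth low-order sinusoids whose amplitudes
# are centred across cycles, so the cycle average reproduces the mean
# curve (and hence the targets) exactly while individual cycles vary.

waveform_target_ids <- function() {
  reg <- gait_feature_registry()
  reg$id[!is.na(reg$variable) & reg$variable != "NA"]
}

infeasible <- function(...) {
  stop_data("infeasible target combination: ", ...)
}

# Control points (percent, value) for one variable's mean curve.
control_points <- function(variable, tg, fo) {
  sw <- 100 - fo
  P <- function(frac_st = NULL, frac_sw = NULL, at = NULL) {
    if (!is.null(at)) return(at)
    if (!is.null(frac_st)) return(round(frac_st * fo))
    fo + round(frac_sw * sw)
  }
  switch(variable,
    pelvic_tilt = {
      T_ <- tg[["max_ant_pelvic_tilt"]]
      cbind(c(0, 50, 100), c(T_ - 2, T_, T_ - 2))
    },
    pelvic_obliquity = {
      R <- tg[["rom_pelvic_obliquity"]]
      if (R < 0) infeasible("negative ROM")
      cbind(c(0, 25, 50, 75, 100), c(0, R / 2, 0, -R / 2, 0))
    },
    pelvic_rotation = {
      R <- tg[["rom_pelvic_rotation"]]
      if (R < 0) infeasible("negative ROM")
      cbind(c(0, 25, 50, 75, 100), c(0, R / 2, 0, -R / 2, 0))
    },
    hip_flexion = {
      m <- tg[["min_hip_flex_stance"]]
      M <- tg[["max_hip_flex_swing"]]
      R <- tg[["rom_hip_sagittal"]]
      if (M <= m) infeasible("swing max <= stance min (hip flexion)")
      if (R < M - m - 1e-9) {
        infeasible("full-cycle hip ROM smaller than swing max - ",
                   "stance min")
      }
      v0 <- m + R
      cbind(c(0, P(0.6), P(frac_sw = 0.6), 100),
            c(v0, m, M, m + 0.8 * (M - m)))
    },
    hip_adduction = {
      ms <- tg[["min_hip_add_stance"]]
      msw <- tg[["min_hip_add_swing"]]
      pv <- max(ms, msw) + 4
      cbind(c(0, P(0.5), fo, P(frac_sw = 0.6), 100),
            c(pv, ms, pv, msw, pv))
    },
    hip_rotation = cbind(c(0, 50, 100), c(2, -2, 2)),
    knee_flexion = {
      Ms <- tg[["max_knee_flex_stance"]]
      ms <- tg[["min_knee_flex_stance"]]
      Msw <- tg[["max_knee_flex_swing"]]
      if (Ms < ms) infeasible("knee stance max < stance min")
      if (!is.na(tg[["rom_knee_sagittal_stance"]]) &&
          abs(tg[["rom_knee_sagittal_stance"]] - (Ms - ms)) > 0.01) {
        infeasible("knee stance ROM must equal stance max - stance min")
      }
      e0 <- ms + 0.3 * (Ms - ms)
      if (Msw < e0) infeasible("knee swing max below loading-response ",
                               "level")
      cbind(c(0, P(0.35), P(0.75), fo, P(frac_sw = 0.55), 100),
            c(e0, Ms, ms, e0, Msw, e0))
    },
    ankle_dorsiflexion = {
      vic <- tg[["dorsiflex_ic"]]
      Mst <- tg[["max_dorsiflex_stance"]]
      Msw <- tg[["max_dorsiflex_swing"]]
      if (Mst < vic) {
        infeasible("stance dorsiflexion max below the initial-contact ",
                   "value")
      }
      low <- min(vic, Msw) - 12
      cbind(c(0, P(0.7), fo, P(frac_sw = 0.5), 100),
            c(vic, Mst, low, Msw, min(vic, Msw) - 2))
    },
    foot_progression = {
      T_ <- tg[["max_foot_prog_stance"]]
      cbind(c(0, P(0.5), fo, P(frac_sw = 0.5), 100),
            c(T_ - 4, T_, T_ - 4, T_ - 6, T_ - 4))
    },
    hip_moment_sagittal = {
      Mx <- tg[["max_hip_ext_mom_stance"]]
      mn <- tg[["min_hip_ext_mom_stance"]]
      if (Mx <= mn) infeasible("hip moment stance max <= min")
      d <- Mx - mn
      cbind(c(0, P(0.25), P(0.75), fo, P(frac_sw = 0.5), 100),
            c(mn + 0.5 * d, Mx, mn, mn + 0.2 * d, mn + 0.4 * d,
              mn + 0.4 * d))
    },
    knee_moment_sagittal = {
      Mx <- tg[["max_knee_ext_mom_stance"]]
      mn <- tg[["min_knee_ext_mom_stance"]]
      if (Mx <= mn) infeasible("knee moment stance max <= min")
      d <- Mx - mn
      cbind(c(0, P(0.25), P(0.75), fo, P(frac_sw = 0.5), 100),
            c(mn + 0.5 * d, Mx, mn, mn + 0.2 * d, mn + 0.4 * d,
              mn + 0.4 * d))
    },
    hip_moment_frontal = {
      Mx <- tg[["max_hip_abd_mom_stance"]]
      cbind(c(0, P(0.4), fo, 100),
            c(Mx - 0.5, Mx, Mx - 0.5, Mx - 0.55))
    },
    ankle_moment_sagittal = {
      mLR <- tg[["min_plantarflex_mom_lr"]]
      MPO <- tg[["max_plantarflex_mom_po"]]
      if (MPO <= mLR) infeasible("push-off ankle moment max <= loading-",
                                 "response min")
      d <- MPO - mLR
      p_po <- round((40 + fo) / 2)
      cbind(c(0, 6, 12, p_po, fo, P(frac_sw = 0.5), 100),
            c(mLR + 0.05 * d, mLR, mLR + 0.05 * d, MPO,
              mLR + 0.2 * d, mLR + 0.05 * d, mLR + 0.1 * d))
    },
    hip_power = {
      Mx <- tg[["max_hip_power_stance"]]
      cbind(c(0, P(0.3), P(0.75), fo, P(frac_sw = 0.5), 100),
            c(Mx - 0.5, Mx, Mx - 1.0, Mx - 0.7, Mx - 0.8, Mx - 0.6))
    },
    ankle_power = {
      mLR <- tg[["min_ankle_power_lr"]]
      MPO <- tg[["max_ankle_power_po"]]
      if (MPO <= mLR) infeasible("push-off ankle power max <= loading-",
                                 "response min")
      d <- MPO - mLR
      p_po <- round((40 + fo) / 2)
      cbind(c(0, 6, 12, p_po, fo, P(frac_sw = 0.5), 100),
            c(mLR + 0.05 * d, mLR, mLR + 0.05 * d, MPO,
              mLR + 0.3 * d, mLR + 0.1 * d, mLR + 0.15 * d))
    },
    stop_spec("no curve family for variable '", variable, "'")
  )
}

mean_curve <- function(variable, tg, fo) {
  cp <- control_points(variable, tg, fo)
  px <- cp[, 1L]
  py <- cp[, 2L]
  keep <- !duplicated(px)
  mono_hermite(px[keep], py[keep], 0:100)
}

#' Default (feasible) waveform feature targets
#'
#' The published DMD baseline medians, adjusted minimally where the
#' medians of independent features are jointly infeasible on a single
#' curve (full-cycle hip ROM is floored at swing max minus stance min;
#' knee stance ROM is derived as stance max minus stance min).
#'
#' @return Named numeric vector over the 26 waveform feature ids.
#' @export
default_waveform_targets <- function() {
  reg <- gait_feature_registry()
  tg <- setNames(reg$ref_median, reg$id)[waveform_target_ids()]
  tg[["rom_hip_sagittal"]] <- max(
    tg[["rom_hip_sagittal"]],
    tg[["max_hip_flex_swing"]] - tg[["min_hip_flex_stance"]]
  )
  tg[["rom_knee_sagittal_stance"]] <-
    tg[["max_knee_flex_stance"]] - tg[["min_knee_flex_stance"]]
  tg[["max_dorsiflex_stance"]] <- max(tg[["max_dorsiflex_stance"]],
                                      tg[["dorsiflex_ic"]])
  tg
}

#' Draw a random feasible waveform target vector
#'
#' Samples the 26 discrete-feature targets uniformly within
#' physiologically plausible ranges, honouring the within-curve
#' consistency constraints by construction (derived ROMs, ordering of
#' extrema).  Used for round-trip testing of the generator/extractor
#' pair.
#'
#' @param seed Integer seed.
#' @return Named numeric vector over the 26 waveform feature ids.
#' @export
random_waveform_targets <- function(seed = 1L) {
  with_seed(seed, {
    U <- function(a, b) runif(1, a, b)
    tg <- c(
      max_ant_pelvic_tilt = U(8, 25),
      rom_pelvic_obliquity = U(4, 15),
      rom_pelvic_rotation = U(6, 20),
      min_hip_flex_stance = U(-15, 5),
      max_hip_flex_swing = NA, rom_hip_sagittal = NA,
      min_hip_add_stance = U(-10, 0),
      min_hip_add_swing = U(-12, -2),
      max_knee_flex_stance = NA, min_knee_flex_stance = U(0, 14),
      rom_knee_sagittal_stance = NA, max_knee_flex_swing = U(55, 75),
      dorsiflex_ic = U(-8, 6), max_dorsiflex_stance = NA,
      max_dorsiflex_swing = U(0, 10),
      max_foot_prog_stance = U(-15, 8),
      max_hip_ext_mom_stance = U(0.2, 1.2),
      min_hip_ext_mom_stance = U(-1.2, -0.2),
      max_hip_abd_mom_stance = U(0.3, 0.9),
      max_knee_ext_mom_stance = U(0.1, 0.7),
      min_knee_ext_mom_stance = U(-0.4, 0),
      min_plantarflex_mom_lr = U(-0.2, -0.01),
      max_plantarflex_mom_po = U(0.7, 1.5),
      min_ankle_power_lr = U(-1.2, -0.2),
      max_ankle_power_po = U(2, 4.5),
      max_hip_power_stance = U(0.2, 1.2)
    )
    tg[["max_hip_flex_swing"]] <- tg[["min_hip_flex_stance"]] + U(25, 50)
    tg[["rom_hip_sagittal"]] <- tg[["max_hip_flex_swing"]] -
      tg[["min_hip_flex_stance"]] + U(0, 6)
    tg[["max_knee_flex_stance"]] <- tg[["min_knee_flex_stance"]] +
      U(15, 35)
    tg[["rom_knee_sagittal_stance"]] <- tg[["max_knee_flex_stance"]] -
      tg[["min_knee_flex_stance"]]
    tg[["max_dorsiflex_stance"]] <- tg[["dorsiflex_ic"]] + U(5, 20)
    tg[waveform_target_ids()]
  })
}

#' Generate a synthetic gait session with prescribed feature targets
#'
#' Constructs smooth mean curves per variable whose windowed extrema
#' equal the requested discrete-feature values (to well within 0.01
#' units), then emits `n_cycles` noisy cycles per variable and side.
#' Per-cycle deviations are smooth sinusoids with amplitudes centred
#' across cycles, so the session's cycle average reproduces the mean
#' curves exactly; infeasible target combinations (e.g., a stance
#' minimum above the stance maximum) raise an error.
#'
#' @param targets Named numeric overrides of
#'   [default_waveform_targets()].
#' @param n_cycles Cycles per variable and side.
#' @param noise_sd Per-cycle deviation amplitude SD for kinematic
#'   curves, degrees; kinetic curves use 5% of this in Nm/kg / W/kg.
#' @param foot_off Foot-off %, an integer in `[45, 75]`.
#' @param seed Integer seed.
#' @param subject,session Identifiers.
#' @param spatiotemporal,age_years,leg_length_m,weight_kg,weaker_side
#'   Session metadata (defaults echo the published DMD baseline
#'   medians).
#' @return A [gait_session()] with both sides populated.
#' @export
simulate_session_waveforms <- function(targets = NULL, n_cycles = 10L,
                                       noise_sd = 1.0, foot_off = 60L,
                                       seed = 1L, subject = "SYN1",
                                       session = "1",
                                       spatiotemporal = list(
                                         cadence = 2.25,
                                         walking_velocity = 0.96,
                                         step_length = 0.43,
                                         step_width = 0.16
                                       ),
                                       age_years = 8.7,
                                       leg_length_m = 0.58,
                                       weight_kg = 23.7,
                                       weaker_side = "left") {
  fo <- as.integer(round(foot_off))
  if (fo < 45L || fo > 75L) {
    stop_data("foot_off must lie in [45, 75] % for the curve families")
  }
  tg <- default_waveform_targets()
  if (!is.null(targets)) {
    bad <- setdiff(names(targets), names(tg))
    if (length(bad)) {
      stop_data("unknown waveform target(s): ",
                paste(bad, collapse = ", "))
    }
    tg[names(targets)] <- targets
  }
  vars <- gait_variables()
  all_vars <- c(vars$kinematic, vars$kinetic)
  means <- lapply(setNames(all_vars, all_vars), mean_curve, tg = tg,
                  fo = fo)
  cycles <- with_seed(seed, {
    out <- list()
    for (sd_ in c("left", "right")) {
      for (v in all_vars) {
        amp_sd <- if (v %in% vars$kinetic) 0.05 * noise_sd else noise_sd
        dev <- matrix(0, 101L, n_cycles)
        for (h in 1:2) {
          ph <- runif(1, 0, 2 * pi)
          a <- rnorm(n_cycles, sd = amp_sd / h)
          a <- a - mean(a)              # cycle average == mean curve
          basis <- sin(2 * pi * h * (0:100) / 100 + ph)
          dev <- dev + outer(basis, a)
        }
        for (k in seq_len(n_cycles)) {
          out[[length(out) + 1L]] <- gait_cycle(
            variable = v, side = sd_,
            samples = means[[v]] + dev[, k],
            foot_off_percent = fo
          )
        }
      }
    }
    out
  })
  gait_session(
    subject = subject, session = session, cycles = cycles,
    age_years = age_years, leg_length_m = leg_length_m,
    weight_kg = weight_kg, spatiotemporal = spatiotemporal,
    weaker_side = weaker_side
  )
}

#' Synthetic typically-developing reference bands
#'
#' Smooth reference mean waveforms for the nine GPS variables,
#' constructed from the same curve families at typical
#' typically-developing feature values.  This is a synthetic stand-in
#' for a clinical reference database, intended for testing and examples.
#'
#' @param foot_off Reference foot-off % (TD stance is about 60%).
#' @return Data frame `variable, percent, value` (9 x 101 rows).
#' @export
synthetic_reference_bands <- function(foot_off = 60L) {
  td <- c(
    max_ant_pelvic_tilt = 11.64, rom_pelvic_obliquity = 7.42,
    rom_pelvic_rotation = 14.93, min_hip_flex_stance = -10.13,
    max_hip_flex_swing = 34.12, rom_hip_sagittal = 45.42,
    min_hip_add_stance = -4.92, min_hip_add_swing = -6.50,
    max_knee_flex_stance = 35.55, min_knee_flex_stance = 3.65,
    rom_knee_sagittal_stance = 31.90, max_knee_flex_swing = 64.75,
    dorsiflex_ic = 0.77, max_dorsiflex_stance = 12.53,
    max_dorsiflex_swing = 5.27, max_foot_prog_stance = 0.11
  )
  tg <- default_waveform_targets()
  tg[names(td)] <- td
  tg[["rom_hip_sagittal"]] <- max(
    tg[["rom_hip_sagittal"]],
    tg[["max_hip_flex_swing"]] - tg[["min_hip_flex_stance"]]
  )
  tg[["rom_knee_sagittal_stance"]] <-
    tg[["max_knee_flex_stance"]] - tg[["min_knee_flex_stance"]]
  rows <- lapply(gait_variables()$gps, function(v) {
    data.frame(variable = v, percent = 0:100,
               value = mean_curve(v, tg, as.integer(foot_off)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
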