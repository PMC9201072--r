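# The 31 predefined gait features: 4 spatiotemporal parameters, 17
# kinematic features (16 discrete + Gait Profile Score), and 10 kinetic
# features, each computed on its phase window of the gait cycle.
#
# Sign conventions: anterior pelvic tilt, hip/knee flexion, hip adduction,
# ankle dorsiflexion, internal foot progression, and internal
# extensor/plantar-flexor moments are positive.

#' Registry of the 31 predefined gait features
#'
#' One row per feature: identifier, human-readable label, unit, feature
#' class, source waveform variable, summary statistic, and phase window.
#' The `ref_median`/`ref_q1`/`ref_q3` columns carry published DMD baseline
#' reference statistics used by the synthetic cohort simulator to set
#' realistic variance scales.
#'
#' @return A data frame with 31 rows.
#' @export
gait_feature_registry <- function() {
  # id, label, unit, class, variable, stat, window, dmd median, Q1, Q3
  f <- function(...) list(...)
  rows <- list(
    f("cadence", "Cadence", "steps/s", "spatiotemporal", NA, NA, NA,
      2.25, 2.01, 2.40),
    f("wv_norm", "WVnorm", "/", "spatiotemporal", NA, NA, NA,
      0.40, 0.37, 0.43),
    f("sw_norm", "SWnorm", "/", "spatiotemporal", NA, NA, NA,
      0.28, 0.24, 0.30),
    f("sl_norm", "SLnorm", "/", "spatiotemporal", NA, NA, NA,
      0.74, 0.70, 0.79),
    f("gps", "Gait profile score", "deg", "kinematic", NA, NA, NA,
      6.81, 5.13, 8.37),
    f("max_ant_pelvic_tilt", "Max anterior pelvic tilt", "deg",
      "kinematic", "pelvic_tilt", "max", "full", 16.36, 14.30, 19.03),
    f("rom_pelvic_obliquity", "ROM pelvic obliquity", "deg",
      "kinematic", "pelvic_obliquity", "rom", "full", 9.62, 7.50, 13.32),
    f("rom_pelvic_rotation", "ROM pelvic rotation", "deg",
      "kinematic", "pelvic_rotation", "rom", "full", 14.41, 9.96, 17.18),
    f("min_hip_flex_stance", "Min hip flex angle stance", "deg",
      "kinematic", "hip_flexion", "min", "stance", -3.08, -7.68, 3.77),
    f("max_hip_flex_swing", "Max hip flex angle swing", "deg",
      "kinematic", "hip_flexion", "max", "swing", 41.81, 34.67, 49.01),
    f("rom_hip_sagittal", "ROM hip sagittal plane", "deg",
      "kinematic", "hip_flexion", "rom", "full", 42.70, 38.90, 46.95),
    f("max_hip_ext_mom_stance", "Max hip ext mom stance", "Nm/kg",
      "kinetic", "hip_moment_sagittal", "max", "stance",
      0.507, 0.388, 0.688),
    f("min_hip_ext_mom_stance", "Min hip ext mom stance", "Nm/kg",
      "kinetic", "hip_moment_sagittal", "min", "stance",
      -0.698, -0.789, -0.516),
    f("max_hip_power_stance", "Max hip power stance", "W/kg",
      "kinetic", "hip_power", "max", "stance", 0.440, 0.334, 0.775),
    f("min_hip_add_stance", "Min hip add angle stance", "deg",
      "kinematic", "hip_adduction", "min", "stance", -6.79, -8.36, -3.96),
    f("min_hip_add_swing", "Min hip add angle swing", "deg",
      "kinematic", "hip_adduction", "min", "swing", -9.45, -11.38, -8.03),
    f("max_hip_abd_mom_stance", "Max hip abd mom stance", "Nm/kg",
      "kinetic", "hip_moment_frontal", "max", "stance",
      0.559, 0.443, 0.735),
    f("max_knee_flex_stance", "Max knee flex angle stance", "deg",
      "kinematic", "knee_flexion", "max", "stance", 35.02, 33.16, 39.36),
    f("min_knee_flex_stance", "Min knee flex angle stance", "deg",
      "kinematic", "knee_flexion", "min", "stance", 9.06, 3.86, 12.31),
    f("rom_knee_sagittal_stance", "ROM knee sagittal plane stance", "deg",
      "kinematic", "knee_flexion", "rom", "stance", 28.01, 24.31, 30.70),
    f("max_knee_flex_swing", "Max knee flex angle swing", "deg",
      "kinematic", "knee_flexion", "max", "swing", 69.48, 64.38, 74.45),
    f("max_knee_ext_mom_stance", "Max knee ext mom stance", "Nm/kg",
      "kinetic", "knee_moment_sagittal", "max", "stance",
      0.414, 0.337, 0.490),
    f("min_knee_ext_mom_stance", "Min knee ext mom stance", "Nm/kg",
      "kinetic", "knee_moment_sagittal", "min", "stance",
      -0.049, -0.120, 0.022),
    f("dorsiflex_ic", "Dorsiflex angle IC", "deg",
      "kinematic", "ankle_dorsiflexion", "ic", "ic", 0.80, -3.61, 4.07),
    f("max_dorsiflex_stance", "Max dorsiflex angle stance", "deg",
      "kinematic", "ankle_dorsiflexion", "max", "stance",
      15.09, 11.34, 17.20),
    f("max_dorsiflex_swing", "Max dorsiflex angle swing", "deg",
      "kinematic", "ankle_dorsiflexion", "max", "swing",
      5.31, 0.02, 6.95),
    f("min_plantarflex_mom_lr", "Min plantar flex mom LR", "Nm/kg",
      "kinetic", "ankle_moment_sagittal", "min", "lr",
      -0.050, -0.088, -0.008),
    f("max_plantarflex_mom_po", "Max plantar flex mom PO", "Nm/kg",
      "kinetic", "ankle_moment_sagittal", "max", "po",
      0.976, 0.864, 1.185),
    f("min_ankle_power_lr", "Min ankle power LR", "W/kg",
      "kinetic", "ankle_power", "min", "lr", -0.501, -0.941, -0.265),
    f("max_ankle_power_po", "Max ankle power PO", "W/kg",
      "kinetic", "ankle_power", "max", "po", 3.022, 2.271, 3.384),
    f("max_foot_prog_stance", "Max int foot prog angle stance", "deg",
      "kinematic", "foot_progression", "max", "stance",
      -7.96, -11.96, -3.13)
  )
  out <- data.frame(
    id = vapply(rows, `[[`, "", 1L),
    label = vapply(rows, `[[`, "", 2L),
    unit = vapply(rows, `[[`, "", 3L),
    class = vapply(rows, `[[`, "", 4L),
    variable = vapply(rows, function(r) as.character(r[[5L]])[1L], ""),
    stat = vapply(rows, function(r) as.character(r[[6L]])[1L], ""),
    window = vapply(rows, function(r) as.character(r[[7L]])[1L], ""),
    ref_median = vapply(rows, `[[`, 0, 8L),
    ref_q1 = vapply(rows, `[[`, 0, 9L),
    ref_q3 = vapply(rows, `[[`, 0, 10L),
    stringsAsFactors = FALSE
  )
  out
}

#' Phase windows of the gait cycle
#'
#' Stance runs from initial contact (0%) to foot-off; swing is the rest of
#' the cycle.  Loading response and push-off are the early-stance
#' weight-acceptance and late-stance propulsion windows.  Percent bounds
#' for LR/PO follow standard gait terminology and are overridable.
#'
#' @param foot_off Foot-off event in % gait cycle.
#' @param lr_end End of loading response (default 12%).
#' @param po_start Start of push-off (default 40%).
#' @return List of `c(lo, hi)` windows in % gait cycle.
#' @export
phase_windows <- function(foot_off, lr_end = 12, po_start = 40) {
  if (!(0 < lr_end && lr_end < po_start && po_start < foot_off &&
        foot_off < 100)) {
    stop_data("degenerate phase windows: need 0 < lr_end < po_start ",
              "< foot_off < 100")
  }
  list(
    full = c(0, 100),
    stance = c(0, foot_off),
    swing = c(foot_off, 100),   # grid points strictly > foot_off
    lr = c(0, lr_end),
    po = c(po_start, foot_off),
    ic = c(0, 0)
  )
}

# Indices (1-based into the 101-grid) of a phase window.  Windows are
# defined on the grid; swing excludes the foot-off point itself.
window_index <- function(window, windows) {
  w <- windows[[window]]
  p <- 0:100
  if (window == "swing") which(p > w[1L] & p <= w[2L])
  else which(p >= w[1L] & p <= w[2L])
}

#' Hof dimensionless normalisation of spatiotemporal parameters
#'
#' Walking velocity is scaled by `sqrt(l * g)`, step length and width by
#' leg length `l`, rendering them dimensionless and comparable across
#' body sizes.
#'
#' @param walking_velocity m/s.
#' @param step_length,step_width m.
#' @param leg_length m, must be positive.
#' @param g Gravitational acceleration, m/s^2.
#' @return Named list with `wv_norm`, `sl_norm`, `sw_norm`.
#' @export
hof_normalize <- function(walking_velocity, step_length, step_width,
                          leg_length, g = 9.81) {
  if (!is.finite(leg_length) || leg_length <= 0) {
    stop_data("leg length must be positive")
  }
  if (g <= 0) stop_data("g must be positive")
  list(
    wv_norm = walking_velocity / sqrt(leg_length * g),
    sl_norm = step_length / leg_length,
    sw_norm = step_width / leg_length
  )
}

#' Extract the 26 discrete waveform features for one side
#'
#' Minima, maxima, ranges of motion, and event values of the averaged
#' kinematic and kinetic waveforms, each computed on its registry-defined
#' phase window (evaluated on the 101-point grid).  Kinetic features are
#' `NA` (absent, not zero) when the session has no kinetic cycles.
#'
#' @param avg A [average_cycles()] result.
#' @param side `"left"` or `"right"`.
#' @param windows Optional [phase_windows()] override; defaults to the
#'   side's mean foot-off with standard LR/PO bounds.
#' @return Named numeric vector over the 26 waveform feature ids.
#' @export
extract_discrete_features <- function(avg, side, windows = NULL) {
  stopifnot(inherits(avg, "gait_avg_session"))
  if (!side %in% names(avg$waveforms)) {
    stop_data("side '", side, "' not present in averaged session")
  }
  wf <- avg$waveforms[[side]]
  if (is.null(windows)) windows <- phase_windows(avg$foot_off[[side]])
  reg <- gait_feature_registry()
  reg <- reg[!is.na(reg$variable) & reg$variable != "NA", ]
  kinetics_absent <- isTRUE(avg$kinetic_cycles[[side]] == 0)
  out <- setNames(rep(NA_real_, nrow(reg)), reg$id)
  for (i in seq_len(nrow(reg))) {
    v <- reg$variable[i]
    if (reg$class[i] == "kinetic" && kinetics_absent) next
    if (is.null(wf[[v]])) {
      if (reg$class[i] == "kinetic") next  # absent kinetics -> NA
      stop_data("missing required waveform '", v, "' on side ", side)
    }
    y <- wf[[v]]
    idx <- window_index(reg$window[i], windows)
    out[reg$id[i]] <- switch(reg$stat[i],
      max = max(y[idx]),
      min = min(y[idx]),
      rom = max(y[idx]) - min(y[idx]),
      ic = y[1L],
      stop_spec("unknown stat ", reg$stat[i])
    )
  }
  out
}

#' Gait Profile Score and per-variable Gait Variable Scores
#'
#' For each of the nine GPS kinematic variables, the Gait Variable Score
#' (GVS) is the root-mean-square difference over the 101-point cycle
#' between the subject's mean waveform and a typically-developing
#' reference mean; the GPS is the root mean square of the nine GVS.
#'
#' @param waveforms Named list of the subject's mean 101-point waveforms
#'   (one analysed side).
#' @param reference Reference bands: data frame with columns
#'   `variable, percent, value` (101 rows per GPS variable), or a named
#'   list of 101-point vectors.
#' @return List with `gps` (degrees) and `gvs` (named, nine entries).
#' @export
compute_gps <- function(waveforms, reference) {
  vars <- gait_variables()$gps
  if (is.data.frame(reference)) {
    reference <- split(reference, reference$variable)
    reference <- lapply(reference, function(d) {
      d$value[order(d$percent)]
    })
  }
  gvs <- setNames(numeric(length(vars)), vars)
  for (v in vars) {
    if (is.null(waveforms[[v]])) {
      stop_data("subject waveform missing GPS variable '", v, "'")
    }
    if (is.null(reference[[v]])) {
      stop_data("reference bands missing GPS variable '", v, "'")
    }
    ref <- reference[[v]]
    if (length(ref) != 101L) {
      stop_data("reference band for '", v, "' must have 101 points")
    }
    gvs[v] <- sqrt(mean((waveforms[[v]] - ref)^2))
  }
  list(gps = sqrt(mean(gvs^2)), gvs = gvs)
}

#' Choose the analysed side of a session
#'
#' The clinically weaker side is analysed when recorded; otherwise a side
#' is drawn uniformly at random under the given seed (deterministic per
#' seed), mirroring the convention of analysing one side per child.
#'
#' @param session A [gait_session()] (or averaged session).
#' @param seed Integer seed for the random draw.
#' @return `"left"` or `"right"`.
#' @export
select_analysis_side <- function(session, seed = 1L) {
  sides <- if (inherits(session, "gait_avg_session")) {
    names(session$waveforms)
  } else {
    session_sides(session)
  }
  ws <- session$weaker_side
  if (ws %in% c("left", "right")) {
    if (!ws %in% sides) {
      stop_data("weaker side '", ws, "' has no cycles in this session")
    }
    return(ws)
  }
  pick <- with_seed(seed, sample(c("left", "right"), 1L))
  if (!pick %in% sides) {
    if (length(sides) == 1L) return(sides)
    stop_data("selected side '", pick, "' absent from session")
  }
  pick
}

#' Compute the full 31-entry feature vector of one session
#'
#' Spatiotemporal parameters (cadence plus Hof-normalised walking
#' velocity, step length, step width), the 26 discrete waveform features
#' of the analysed side, and the Gait Profile Score.
#'
#' @param session A [gait_session()].
#' @param reference GPS reference bands (see [compute_gps()]).
#' @param side Analysed side; default chooses via
#'   [select_analysis_side()].
#' @param seed Seed for random side selection.
#' @param g Gravitational acceleration for Hof normalisation.
#' @param windows Optional phase-window override.
#' @return One-row data frame: `subject`, `session`, `analysed_side`,
#'   then the 31 features by id.
#' @export
session_features <- function(session, reference, side = NULL, seed = 1L,
                             g = 9.81, windows = NULL) {
  avg <- average_cycles(session)
  if (is.null(side)) side <- select_analysis_side(session, seed = seed)
  if (!side %in% names(avg$waveforms)) {
    stop_data("requested side '", side, "' absent from session")
  }
  st <- avg$spatiotemporal
  need <- c("cadence", "walking_velocity", "step_length", "step_width")
  stv <- vapply(need, function(nm) {
    if (is.null(st[[nm]])) NA_real_ else as.numeric(st[[nm]])
  }, 0)
  hn <- if (all(is.finite(stv[-1L])) && is.finite(avg$leg_length_m)) {
    hof_normalize(stv[["walking_velocity"]], stv[["step_length"]],
                  stv[["step_width"]], avg$leg_length_m, g = g)
  } else {
    list(wv_norm = NA_real_, sl_norm = NA_real_, sw_norm = NA_real_)
  }
  disc <- extract_discrete_features(avg, side, windows = windows)
  gps <- compute_gps(avg$waveforms[[side]], reference)$gps
  vals <- c(
    cadence = unname(stv[["cadence"]]), wv_norm = hn$wv_norm,
    sw_norm = hn$sw_norm, sl_norm = hn$sl_norm, gps = gps, disc
  )
  reg <- gait_feature_registry()
  stopifnot(all(reg$id %in% names(vals)))
  out <- data.frame(subject = avg$subject, session = avg$session,
                    analysed_side = side, age_years = avg$age_years,
                    stringsAsFactors = FALSE)
  for (id in reg$id) out[[id]] <- unname(vals[[id]])
  out
}

#' Read GPS reference bands from a delimited table
#'
#' @param path CSV with columns `variable, percent, value`.
#' @return Data frame usable as `reference` in [compute_gps()].
#' @export
read_reference_bands <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("variable", "percent", "value")
  if (!all(need %in% names(tab))) {
    stop_data("reference band table needs columns ",
              paste(need, collapse = ", "))
  }
  tab
}
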