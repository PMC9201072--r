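# Per-cycle gait waveform data model and I/O.
#
# A "cycle" is one variable's trajectory over one gait cycle, resampled to
# the canonical 101-point grid (0, 1, ..., 100 % of the cycle).  Cycles are
# grouped into sessions (one 3D gait analysis visit of one subject), and a
# session is averaged per variable and side before feature extraction.

#' Gait variable names
#'
#' Canonical variable identifiers used throughout the package.  Kinematic
#' variables are joint/segment angles in degrees; kinetic variables are
#' bodyweight-normalised internal joint moments (Nm/kg) and powers (W/kg).
#'
#' @return A list with components `kinematic`, `kinetic`, and `gps` (the
#'   nine kinematic variables entering the Gait Profile Score).
#' @export
gait_variables <- function() {
  kinematic <- c(
    "pelvic_tilt", "pelvic_obliquity", "pelvic_rotation",
    "hip_flexion", "hip_adduction", "hip_rotation",
    "knee_flexion", "ankle_dorsiflexion", "foot_progression"
  )
  kinetic <- c(
    "hip_moment_sagittal", "hip_moment_frontal", "knee_moment_sagittal",
    "ankle_moment_sagittal", "hip_power", "ankle_power"
  )
  list(kinematic = kinematic, kinetic = kinetic, gps = kinematic)
}

variable_units <- function(variable) {
  v <- gait_variables()
  ifelse(variable %in% v$kinematic, "deg",
    ifelse(grepl("moment", variable), "Nm/kg", "W/kg")
  )
}

#' Construct a single gait waveform cycle
#'
#' @param variable One of [gait_variables()].
#' @param side `"left"` or `"right"`.
#' @param samples Numeric vector of length 101, sample `i` at `(i-1)`% of
#'   the gait cycle.
#' @param foot_off_percent Foot-off (toe-off) event, strictly inside
#'   (0, 100)% of the cycle; stance ends here.
#' @return An object of class `"gait_cycle"`.
#' @export
gait_cycle <- function(variable, side, samples, foot_off_percent = 60) {
  v <- gait_variables()
  if (!variable %in% c(v$kinematic, v$kinetic)) {
    stop_data("unknown gait variable '", variable, "'")
  }
  side <- match.arg(side, c("left", "right"))
  samples <- as.numeric(samples)
  if (length(samples) != 101L || anyNA(samples)) {
    stop_data("a gait cycle requires exactly 101 finite samples, got ",
              length(samples))
  }
  if (!is.finite(foot_off_percent) ||
      foot_off_percent <= 0 || foot_off_percent >= 100) {
    stop_data("foot_off_percent must lie strictly inside (0, 100)")
  }
  structure(
    list(variable = variable, side = side, samples = samples,
         units = variable_units(variable),
         foot_off_percent = foot_off_percent),
    class = "gait_cycle"
  )
}

#' Construct a gait analysis session
#'
#' One measurement visit of one subject: a set of per-cycle waveforms plus
#' session-level metadata (age, leg length, spatiotemporal parameters,
#' clinically determined weaker side).
#'
#' @param subject,session Identifiers.
#' @param cycles List of [gait_cycle()] objects.
#' @param age_years,leg_length_m,weight_kg Session metadata; `age_years`
#'   and `leg_length_m` must be positive when given.
#' @param spatiotemporal Named list/vector with `cadence` (steps/s),
#'   `walking_velocity` (m/s), `step_length` (m), `step_width` (m).
#' @param weaker_side `"left"`, `"right"`, or `"unknown"`.
#' @return An object of class `"gait_session"`.
#' @export
gait_session <- function(subject, session, cycles,
                         age_years = NA_real_, leg_length_m = NA_real_,
                         weight_kg = NA_real_,
                         spatiotemporal = list(),
                         weaker_side = "unknown") {
  weaker_side <- match.arg(weaker_side, c("left", "right", "unknown"))
  if (!is.na(age_years) && age_years <= 0) stop_data("age must be > 0")
  if (!is.na(leg_length_m) && leg_length_m <= 0) {
    stop_data("leg length must be > 0")
  }
  if (!all(vapply(cycles, inherits, logical(1), "gait_cycle"))) {
    stop_data("`cycles` must be a list of gait_cycle objects")
  }
  structure(
    list(subject = as.character(subject), session = as.character(session),
         age_years = age_years, leg_length_m = leg_length_m,
         weight_kg = weight_kg,
         spatiotemporal = as.list(spatiotemporal),
         weaker_side = weaker_side, cycles = cycles),
    class = "gait_session"
  )
}

session_sides <- function(x) unique(vapply(x$cycles, `[[`, "", "side"))

# Shape-preserving piecewise-cubic Hermite interpolation.  Slopes follow
# Fritsch-Butland (weighted harmonic mean of adjacent secants), zeroed at
# local extrema of the data, so the interpolant is monotone on every
# segment and never overshoots a data point.  (stats::splinefun's
# "monoH.FC" only filters slopes inside monotone runs and can overshoot
# at interior extrema, which would corrupt windowed min/max features.)
mono_hermite <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  S <- diff(y) / h
  m <- numeric(n)
  m[1L] <- S[1L]
  m[n] <- S[n - 1L]
  if (n > 2L) {
    for (i in 2:(n - 1L)) {
      if (S[i - 1L] * S[i] <= 0) {
        m[i] <- 0
      } else {
        w1 <- 2 * h[i] + h[i - 1L]
        w2 <- h[i] + 2 * h[i - 1L]
        m[i] <- (w1 + w2) / (w1 / S[i - 1L] + w2 / S[i])
      }
    }
  }
  seg <- findInterval(xout, x, rightmost.closed = TRUE)
  seg[seg < 1L] <- 1L
  seg[seg >= n] <- n - 1L
  t_ <- (xout - x[seg]) / h[seg]
  h00 <- (1 + 2 * t_) * (1 - t_)^2
  h10 <- t_ * (1 - t_)^2
  h01 <- t_^2 * (3 - 2 * t_)
  h11 <- t_^2 * (t_ - 1)
  h00 * y[seg] + h10 * h[seg] * m[seg] +
    h01 * y[seg + 1L] + h11 * h[seg] * m[seg + 1L]
}

#' Resample one gait cycle to the canonical 101-point grid
#'
#' Monotone-safe piecewise-cubic Hermite interpolation (Fritsch-Butland
#' slopes) of a waveform sampled on an arbitrary 0-100% grid onto the
#' integer grid 0, 1, ..., 100.  The interpolant passes through all input
#' points without overshoot at extrema, so inputs already on the canonical
#' grid are returned unchanged and endpoints are preserved exactly.
#'
#' @param samples Numeric vector (length >= 4) of waveform values.
#' @param grid Strictly increasing numeric vector of the same length,
#'   spanning `[0, 100]` (percent of gait cycle).
#' @return Numeric vector of length 101.
#' @export
resample_cycle <- function(samples, grid) {
  samples <- as.numeric(samples)
  grid <- as.numeric(grid)
  if (length(samples) != length(grid)) {
    stop_data("samples and grid lengths differ")
  }
  if (length(samples) < 4L) {
    stop_data("need at least 4 samples to resample a cycle, got ",
              length(samples))
  }
  if (anyNA(samples) || anyNA(grid)) stop_data("NA in cycle samples or grid")
  if (any(diff(grid) <= 0)) stop_data("cycle grid is not strictly increasing")
  if (grid[1L] != 0 || grid[length(grid)] != 100) {
    stop_data("cycle grid must span [0, 100]")
  }
  if (length(grid) == 101L && all(grid == 0:100)) return(samples)
  out <- mono_hermite(grid, samples, 0:100)
  out[1L] <- samples[1L]
  out[101L] <- samples[length(samples)]
  out
}

#' Read per-cycle gait waveforms from long-format tables
#'
#' Assembles [gait_session()] objects from delimited text tables.  The
#' cycle table is long format with one row per sample; cycles on grids
#' other than the canonical 0..100 step-1 grid are passed through
#' [resample_cycle()].
#'
#' @param cycles_path CSV with columns
#'   `subject,session,side,variable,cycle,percent,value`.
#' @param events_path Optional CSV with columns
#'   `subject,session,side,cycle,foot_off_percent`; cycles without an
#'   event row get `default_foot_off`.
#' @param sessions_path Optional CSV with columns
#'   `subject,session,age_years,leg_length_m,weight_kg,cadence,
#'   walking_velocity,step_length,step_width,weaker_side`.
#' @param default_foot_off Foot-off used when no events table is given.
#' @return A list of `gait_session` objects.
#' @export
read_cycles <- function(cycles_path, events_path = NULL,
                        sessions_path = NULL, default_foot_off = 60) {
  tab <- read.csv(cycles_path, stringsAsFactors = FALSE)
  required <- c("subject", "session", "side", "variable", "cycle",
                "percent", "value")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop_data("cycle table is missing required column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  bad <- !is.finite(tab$percent) | !is.finite(tab$value)
  if (any(bad)) {
    stop_data("malformed cycle rows (non-numeric percent/value) at line(s) ",
              paste(head(which(bad) + 1L, 10L), collapse = ", "))
  }
  key <- interaction(tab$subject, tab$session, tab$side, tab$variable,
                     tab$cycle, tab$percent, drop = TRUE)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop_data("duplicate (cycle, percent) rows at line(s) ",
              paste(head(dup + 1L, 10L), collapse = ", "))
  }

  events <- NULL
  if (!is.null(events_path)) {
    events <- read.csv(events_path, stringsAsFactors = FALSE)
    ereq <- c("subject", "session", "side", "cycle", "foot_off_percent")
    if (!all(ereq %in% names(events))) {
      stop_data("events table is missing required column(s): ",
                paste(setdiff(ereq, names(events)), collapse = ", "))
    }
  }
  meta <- NULL
  if (!is.null(sessions_path)) {
    meta <- read.csv(sessions_path, stringsAsFactors = FALSE)
    if (!all(c("subject", "session") %in% names(meta))) {
      stop_data("session table needs subject and session columns")
    }
  }

  lookup_foot_off <- function(subj, sess, side, cyc) {
    if (is.null(events)) return(default_foot_off)
    hit <- events$subject == subj & events$session == sess &
      events$side == side & events$cycle == cyc
    if (!any(hit)) return(default_foot_off)
    events$foot_off_percent[which(hit)[1L]]
  }

  out <- list()
  for (sk in split(tab, interaction(tab$subject, tab$session, drop = TRUE))) {
    subj <- sk$subject[1L]
    sess <- sk$session[1L]
    cycles <- list()
    for (ck in split(sk, interaction(sk$side, sk$variable, sk$cycle,
                                     drop = TRUE))) {
      ck <- ck[order(ck$percent), , drop = FALSE]
      samples <- resample_cycle(ck$value, ck$percent)
      cycles[[length(cycles) + 1L]] <- gait_cycle(
        variable = ck$variable[1L], side = ck$side[1L], samples = samples,
        foot_off_percent = lookup_foot_off(subj, sess, ck$side[1L],
                                           ck$cycle[1L])
      )
    }
    args <- list(subject = subj, session = sess, cycles = cycles)
    if (!is.null(meta)) {
      hit <- meta$subject == subj & meta$session == sess
      if (any(hit)) {
        m <- meta[which(hit)[1L], ]
        getm <- function(col) {
          if (col %in% names(m)) m[[col]] else NA_real_
        }
        args$age_years <- getm("age_years")
        args$leg_length_m <- getm("leg_length_m")
        args$weight_kg <- getm("weight_kg")
        args$spatiotemporal <- list(
          cadence = getm("cadence"),
          walking_velocity = getm("walking_velocity"),
          step_length = getm("step_length"),
          step_width = getm("step_width")
        )
        ws <- if ("weaker_side" %in% names(m)) m$weaker_side else "unknown"
        if (is.na(ws) || !nzchar(ws)) ws <- "unknown"
        args$weaker_side <- ws
      }
    }
    out[[paste(subj, sess, sep = "/")]] <- do.call(gait_session, args)
  }
  out[order(names(out))]
}

#' Write sessions back to long-format tables
#'
#' Inverse of [read_cycles()]; values are written with 17 significant
#' digits so a write/read round trip reproduces them to full double
#' precision.
#'
#' @param sessions List of `gait_session` objects.
#' @param cycles_path,events_path,sessions_path Output CSV paths
#'   (`NULL` skips the table).
#' @return Invisibly, the cycle table as a data frame.
#' @export
write_cycles <- function(sessions, cycles_path, events_path = NULL,
                         sessions_path = NULL) {
  num <- function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  }
  rows <- list()
  ev <- list()
  meta <- list()
  for (s in sessions) {
    cyc_idx <- integer()
    for (cy in s$cycles) {
      k <- paste(cy$side, cy$variable)
      cyc_idx[k] <- if (k %in% names(cyc_idx)) cyc_idx[[k]] + 1L else 1L
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s$subject, session = s$session, side = cy$side,
        variable = cy$variable, cycle = cyc_idx[[k]], percent = 0:100,
        value = num(cy$samples), stringsAsFactors = FALSE
      )
      ev[[length(ev) + 1L]] <- data.frame(
        subject = s$subject, session = s$session, side = cy$side,
        cycle = cyc_idx[[k]], variable = cy$variable,
        foot_off_percent = num(cy$foot_off_percent),
        stringsAsFactors = FALSE
      )
    }
    st <- s$spatiotemporal
    getst <- function(nm) if (!is.null(st[[nm]])) st[[nm]] else NA_real_
    meta[[length(meta) + 1L]] <- data.frame(
      subject = s$subject, session = s$session,
      age_years = num(s$age_years), leg_length_m = num(s$leg_length_m),
      weight_kg = num(s$weight_kg), cadence = num(getst("cadence")),
      walking_velocity = num(getst("walking_velocity")),
      step_length = num(getst("step_length")),
      step_width = num(getst("step_width")),
      weaker_side = s$weaker_side, stringsAsFactors = FALSE
    )
  }
  cyc_tab <- do.call(rbind, rows)
  write.csv(cyc_tab, cycles_path, row.names = FALSE, quote = FALSE)
  if (!is.null(events_path)) {
    # one event row per (side, variable, cycle); readers match on cycle id
    etab <- do.call(rbind, ev)
    etab <- etab[!duplicated(etab[c("subject", "session", "side",
                                    "cycle")]), ]
    etab$variable <- NULL
    write.csv(etab, events_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(sessions_path)) {
    write.csv(do.call(rbind, meta), sessions_path, row.names = FALSE,
              quote = FALSE)
  }
  invisible(cyc_tab)
}

#' Average a session's cycles per variable and side
#'
#' Pointwise arithmetic mean of all cycles of each (variable, side), and
#' the mean foot-off percentage per side.  Sides are never pooled.  A
#' session may legitimately lack kinetic cycles (no clean force-plate
#' strikes); kinetic waveforms are then marked absent, never zero-filled.
#'
#' @param session A [gait_session()].
#' @param required_kinematic Kinematic variables that must be present on
#'   every analysed side (defaults to all nine).
#' @return An object of class `"gait_avg_session"` with per-side lists of
#'   mean 101-point waveforms.
#' @export
average_cycles <- function(session,
                           required_kinematic = gait_variables()$kinematic) {
  stopifnot(inherits(session, "gait_session"))
  sides <- session_sides(session)
  if (!length(sides)) stop_data("session has no cycles")
  waveforms <- list()
  foot_off <- list()
  kinetic_n <- list()
  for (sd in sides) {
    cyc <- Filter(function(cy) cy$side == sd, session$cycles)
    vars <- unique(vapply(cyc, `[[`, "", "variable"))
    miss <- setdiff(required_kinematic, vars)
    if (length(miss)) {
      stop_data("side '", sd, "' lacks required kinematic variable(s): ",
                paste(miss, collapse = ", "))
    }
    wf <- list()
    for (v in vars) {
      mats <- vapply(Filter(function(cy) cy$variable == v, cyc),
                     `[[`, numeric(101), "samples")
      wf[[v]] <- rowMeans(as.matrix(mats))
    }
    n_kin <- sum(vapply(cyc, function(cy) {
      cy$variable %in% gait_variables()$kinematic
    }, logical(1)))
    n_kinetic <- length(cyc) - n_kin
    waveforms[[sd]] <- wf
    foot_off[[sd]] <- mean(vapply(cyc, `[[`, 0, "foot_off_percent"))
    kinetic_n[[sd]] <- n_kinetic
  }
  structure(
    list(subject = session$subject, session = session$session,
         waveforms = waveforms, foot_off = foot_off,
         kinetic_cycles = kinetic_n,
         spatiotemporal = session$spatiotemporal,
         age_years = session$age_years,
         leg_length_m = session$leg_length_m,
         weaker_side = session$weaker_side),
    class = "gait_avg_session"
  )
}
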