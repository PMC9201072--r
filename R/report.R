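# Batch drivers and report rendering: session tables in, feature tables
# out, per-response longitudinal datasets, and fixed-effects summary
# tables shaped like the published per-feature model reports.

#' Extract the feature table of a session collection
#'
#' One row of 31 features per (subject, session); kinetic features of
#' sessions without kinetic cycles are `NA` (reported, not zero-filled).
#'
#' @param sessions List of [gait_session()] objects (e.g., from
#'   [read_cycles()]).
#' @param reference GPS reference bands (see [compute_gps()]).
#' @param seed Seed for random side selection of sessions without a
#'   recorded weaker side.
#' @param g Gravitational acceleration for Hof normalisation.
#' @return Data frame, one row per session.
#' @export
extract_gait_features <- function(sessions, reference, seed = 1L,
                                  g = 9.81) {
  if (!length(sessions)) stop_data("no sessions to extract")
  rows <- lapply(sessions, function(s) {
    session_features(s, reference, seed = seed, g = g)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(is.na(out[gait_feature_registry()$id]))) {
    warning("some sessions have absent kinetic features (no kinetic ",
            "cycles); reported as NA")
  }
  out
}

#' Write / read a wide feature table
#'
#' Delimited text with header; labels follow the feature registry.
#' Missing kinetics are written as empty fields.
#'
#' @param features Feature table from [extract_gait_features()].
#' @param path Output CSV path.
#' @export
write_features_table <- function(features, path) {
  write.csv(features, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_features_table
#' @export
read_features_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Build per-response longitudinal datasets from a feature table
#'
#' Converts a wide feature table (with `subject` and `age_years`
#' columns) into one [lmm_data()] per requested response.  Time is years
#' since each subject's first session (`age_years` minus the subject's
#' baseline age); baseline age is centred at the cohort minimum.
#' Sessions with a missing response value are dropped for that response.
#'
#' @param features Feature table.
#' @param responses Feature ids to model (default: all 31).
#' @return Named list of `lmm_data` objects.
#' @export
longitudinal_datasets <- function(features,
                                  responses = gait_feature_registry()$id) {
  stopifnot(all(c("subject", "age_years") %in% names(features)))
  reg <- gait_feature_registry()
  base_age <- tapply(features$age_years, features$subject, min)
  time <- features$age_years -
    as.numeric(base_age[features$subject])
  out <- lapply(responses, function(id) {
    keep <- is.finite(features[[id]])
    unit <- reg$unit[match(id, reg$id)]
    lmm_data(features$subject[keep], time[keep],
             as.numeric(base_age[features$subject[keep]]),
             features[[id]][keep], response = id, units = unit)
  })
  names(out) <- responses
  out
}

#' Render a fixed-effects summary table from workflow reports
#'
#' One row per response with the retained coefficient estimates and
#' their robust Wald p-values, significance starred at `alpha`, grouped
#' by longitudinal (time), cross-sectional (baseline age), and
#' interaction terms.
#'
#' @param reports Output of [run_longitudinal_analysis()].
#' @param alpha Starring level.
#' @return Data frame of class `"gait_fe_table"`.
#' @export
render_fixed_effects_table <- function(reports, alpha = 0.05) {
  if (inherits(reports, "gait_workflow_report")) {
    reports <- list(reports)
  }
  terms <- c("(Intercept)", LMM_TERMS)
  rows <- lapply(reports, function(r) {
    row <- data.frame(response = r$response, stringsAsFactors = FALSE)
    if (!is.null(r$error)) {
      row$status <- "failed"
      for (tm in terms) row[[tm]] <- NA_character_
      return(row)
    }
    row$status <- "ok"
    fit <- r$fit
    for (tm in terms) {
      if (tm %in% names(fit$beta)) {
        est <- fit$beta[[tm]]
        pv <- if (tm == "(Intercept)") {
          robust_wald_f(fit, "(Intercept)")$p
        } else {
          robust_wald_f(fit, tm)$p
        }
        row[[tm]] <- sprintf("%.3f%s", est,
                             if (pv < alpha) "*" else "")
      } else {
        row[[tm]] <- ""
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gait_fe_table", class(out))
  out
}
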