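# Longitudinal dataset container and fixed/random design construction for
# the mixed cross-sectional longitudinal model
#
#   y_ij = b0 + b1 t_ij + b2 t_ij^2 + b3 a_i + b4 a_i^2 + b5 a_i^3
#          + b6 t_ij a_i + u_1i + u_2i t_ij + e1_ij + e2_ij
#
# where t is years since the subject's first included session, a is the
# centred baseline age (baseline age minus the cohort minimum, so the
# intercept is the response at the youngest baseline age and time zero),
# u are subject-level random effects, e1 iid measurement error, and e2 an
# optional stationary serial-correlation process.

LMM_TERMS <- c("time", "time2", "age", "age2", "age3", "time_age")

#' Longitudinal dataset for mixed-model fitting
#'
#' @param subject Subject identifiers.
#' @param time Years since each subject's first included session; every
#'   subject must have a time-0 row.
#' @param baseline_age Baseline age in years (constant within subject).
#' @param value Response values.
#' @param response,units Response name and units (metadata).
#' @param center_age Reference age subtracted from `baseline_age`;
#'   defaults to the cohort minimum.  Centred ages must be non-negative.
#' @return A data frame of class `"lmm_data"` with columns `subject`,
#'   `time`, `baseline_age`, `age` (centred), `value`.
#' @export
lmm_data <- function(subject, time, baseline_age, value,
                     response = "response", units = "", center_age = NULL) {
  subject <- as.character(subject)
  time <- as.numeric(time)
  baseline_age <- as.numeric(baseline_age)
  value <- as.numeric(value)
  n <- length(subject)
  if (length(time) != n || length(baseline_age) != n ||
      length(value) != n) {
    stop_data("subject, time, baseline_age, value lengths differ")
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    stop_data("time must be finite and non-negative")
  }
  by_subj <- split(seq_len(n), subject)
  for (idx in by_subj) {
    if (sum(time[idx] == 0) != 1L) {
      stop_data("each subject needs exactly one time-0 (baseline) row; ",
                "subject '", subject[idx[1L]], "' has ",
                sum(time[idx] == 0))
    }
    if (length(unique(baseline_age[idx])) != 1L) {
      stop_data("baseline_age varies within subject '",
                subject[idx[1L]], "'")
    }
  }
  if (is.null(center_age)) center_age <- min(baseline_age)
  age <- baseline_age - center_age
  if (any(age < -1e-9)) {
    stop_data("centred baseline age is negative; center_age too large")
  }
  out <- data.frame(subject = subject, time = time,
                    baseline_age = baseline_age, age = pmax(age, 0),
                    value = value, stringsAsFactors = FALSE)
  attr(out, "response") <- response
  attr(out, "units") <- units
  attr(out, "center_age") <- center_age
  class(out) <- c("lmm_data", "data.frame")
  out
}

#' Mixed-model specification
#'
#' Fixed terms are a subset of `time`, `time2`, `age`, `age2`, `age3`,
#' `time_age` (the intercept is always included); the polynomial
#' hierarchy is enforced (`time2` requires `time`; `age3` requires `age2`
#' requires `age`; the interaction requires both mains).  The random
#' structure is a subject-level intercept or intercept plus time slope;
#' the serial structure is none, Gaussian (`exp(-u^2/phi^2)`), or
#' exponential (`exp(-u/phi)`) in the within-subject time lag `u`.
#'
#' @param fixed Character vector of fixed terms (beyond the intercept).
#' @param random `"intercept"` or `"intercept_slope"`.
#' @param serial `"none"`, `"gaussian"`, or `"exponential"`.
#' @return An object of class `"lmm_spec"`.
#' @export
lmm_spec <- function(fixed = c("time", "age", "time_age"),
                     random = c("intercept_slope", "intercept"),
                     serial = c("none", "gaussian", "exponential")) {
  random <- match.arg(random)
  serial <- match.arg(serial)
  fixed <- unique(as.character(fixed))
  bad <- setdiff(fixed, LMM_TERMS)
  if (length(bad)) {
    stop_spec("unknown fixed term(s): ", paste(bad, collapse = ", "))
  }
  requires <- list(
    time2 = "time", age2 = "age", age3 = c("age", "age2"),
    time_age = c("time", "age")
  )
  for (tm in intersect(fixed, names(requires))) {
    miss <- setdiff(requires[[tm]], fixed)
    if (length(miss)) {
      stop_spec("fixed term '", tm, "' requires ",
                paste(miss, collapse = " and "),
                " (polynomial hierarchy)")
    }
  }
  structure(
    list(fixed = LMM_TERMS[LMM_TERMS %in% fixed], random = random,
         serial = serial),
    class = "lmm_spec"
  )
}

#' @export
print.lmm_spec <- function(x, ...) {
  cat("lmm_spec: value ~ 1",
      if (length(x$fixed)) paste("+", paste(x$fixed, collapse = " + ")),
      "\n  random:", x$random, "  serial:", x$serial, "\n")
  invisible(x)
}

# Stacked fixed-effect design (always a matrix, also for n = 1).
fixed_matrix <- function(fixed, time, age) {
  n <- length(time)
  X <- matrix(1, n, 1L + length(fixed))
  for (k in seq_along(fixed)) {
    X[, k + 1L] <- term_column(fixed[k], time, age)
  }
  X
}

term_column <- function(term, time, age) {
  switch(term,
    time = time, time2 = time^2, age = age, age2 = age^2, age3 = age^3,
    time_age = time * age,
    stop_spec("unknown term ", term)
  )
}

#' Build per-subject fixed and random design matrices
#'
#' @param data An [lmm_data()].
#' @param spec An [lmm_spec()].
#' @return List of class `"lmm_design"`: per-subject blocks `X` (fixed
#'   design, canonical column order), `Z` (`[1]` or `[1, time]`), `y`,
#'   `times`, plus the stacked `X`, `y`, and bookkeeping.
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(data, "lmm_data"), inherits(spec, "lmm_spec"))
  cols <- c("(Intercept)", spec$fixed)
  Xfull <- fixed_matrix(spec$fixed, data$time, data$age)
  colnames(Xfull) <- cols
  q <- if (spec$random == "intercept_slope") 2L else 1L
  subjects <- unique(data$subject)
  blocks <- lapply(subjects, function(s) {
    idx <- which(data$subject == s)
    Z <- if (q == 2L) cbind(1, data$time[idx]) else
      matrix(1, length(idx), 1L)
    list(X = Xfull[idx, , drop = FALSE], Z = Z,
         y = data$value[idx], times = data$time[idx], subject = s,
         idx = idx)
  })
  names(blocks) <- subjects
  structure(
    list(blocks = blocks, X = Xfull, y = data$value, q = q,
         p = length(cols), n = nrow(data), subjects = subjects,
         spec = spec),
    class = "lmm_design"
  )
}
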