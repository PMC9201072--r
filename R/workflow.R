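# Five-step model-building workflow, applied per gait feature:
#
#   1. explore the average trend with loess smooths of the response
#      against time and against baseline age, and pick the lowest
#      polynomial orders that reproduce the smooths;
#   2. choose the preliminary random structure from the observed variance
#      function (squared OLS residuals against time);
#   3. choose the serial-correlation structure by comparing the REML
#      likelihoods of the no-serial, Gaussian, and exponential models;
#   4. test whether the random slope can be dropped with the boundary
#      mixture chi-square LRT;
#   5. backward-eliminate non-significant fixed effects with
#      sandwich-robust Wald F tests (no multiplicity correction,
#      hierarchy-respecting).
#
# Steps 1-2 mechanise what is traditionally done by visual inspection;
# their tolerances are exposed in the workflow configuration so the
# judgement calls are explicit and reproducible.

#' Workflow configuration
#'
#' @param alpha Significance level for fixed-effect elimination and the
#'   random-slope LRT.
#' @param span Loess span for trend exploration.
#' @param poly_tol Fraction of the loess smooth's range that a polynomial
#'   approximation may miss (RMS) and still be accepted.
#' @param max_time_degree,max_age_degree Polynomial caps (2 and 3).
#' @param serial_candidates Serial structures compared in step 3.
#' @param serial_aic_margin Serial correlation is retained only when it
#'   improves AIC over the no-serial model (2 extra parameters); this is
#'   the deliberate information-criterion reading of the likelihood
#'   comparison, since the richer structure never loses on likelihood
#'   alone.
#' @param outlier_removal Refit without empirical-Bayes-flagged subjects?
#' @param outlier_level Chi-square flagging quantile.
#' @param seed Seed controlling all workflow randomness.
#' @param fit_options Options passed to [reml_fit()].
#' @return List of class `"gait_workflow_config"`.
#' @export
workflow_config <- function(alpha = 0.05, span = 0.75, poly_tol = 0.02,
                            max_time_degree = 2L, max_age_degree = 3L,
                            serial_candidates = c("none", "gaussian",
                                                  "exponential"),
                            serial_aic_margin = 0,
                            outlier_removal = FALSE, outlier_level = 0.99,
                            seed = 1L, fit_options = list()) {
  structure(
    list(alpha = alpha, span = span, poly_tol = poly_tol,
         max_time_degree = max_time_degree,
         max_age_degree = max_age_degree,
         serial_candidates = serial_candidates,
         serial_aic_margin = serial_aic_margin,
         outlier_removal = outlier_removal,
         outlier_level = outlier_level, seed = seed,
         fit_options = fit_options),
    class = "gait_workflow_config"
  )
}

# Lowest polynomial degree (<= max_degree) whose least-squares fit to the
# loess smooth stays within tol_frac of the smooth's range (RMS).
smooth_poly_degree <- function(x, y, span, max_degree, tol_frac) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  lo <- tryCatch(
    loess(y ~ x, span = span, degree = 2,
          family = "gaussian",
          control = loess.control(surface = "direct")),
    error = function(e) NULL
  )
  grid <- seq(min(x), max(x), length.out = 50L)
  sm <- if (is.null(lo)) rep(mean(y), 50L) else predict(lo, grid)
  rng <- diff(range(sm))
  if (!is.finite(rng) || rng < .Machine$double.eps^0.5) return(0L)
  # a smooth whose whole range is below the residual noise level carries
  # no trend worth a polynomial term
  noise_sd <- if (is.null(lo)) 0 else sd(resid(lo))
  if (rng < noise_sd) return(0L)
  for (d in 0:max_degree) {
    fit <- if (d == 0) lm(sm ~ 1) else lm(sm ~ poly(grid, d, raw = TRUE))
    if (sqrt(mean(resid(fit)^2)) <= tol_frac * rng) return(d)
  }
  max_degree
}

#' Step 1: explore the mean structure
#'
#' Loess smooths of the response against time and against baseline age
#' determine the lowest polynomial degrees (time capped at 2, baseline
#' age at 3) that reproduce the average trends; the time-by-baseline-age
#' interaction is always included a priori in the preliminary structure,
#' and both linear mains are floored in (the interaction requires them).
#'
#' @param data An [lmm_data()].
#' @param config A [workflow_config()].
#' @return Character vector of preliminary fixed terms.
#' @export
explore_mean_structure <- function(data, config = workflow_config()) {
  stopifnot(inherits(data, "lmm_data"))
  pts <- unique(data.frame(t = data$time, a = data$age))
  if (nrow(pts) < 10L) {
    stop_data("need at least 10 distinct (time, baseline age) points")
  }
  d_time <- smooth_poly_degree(data$time, data$value, config$span,
                               config$max_time_degree, config$poly_tol)
  d_age <- smooth_poly_degree(data$age, data$value, config$span,
                              config$max_age_degree, config$poly_tol)
  fixed <- c("time", "age", "time_age")
  if (d_time >= 2) fixed <- c(fixed, "time2")
  if (d_age >= 2) fixed <- c(fixed, "age2")
  if (d_age >= 3) fixed <- c(fixed, "age3")
  lmm_spec(fixed = fixed, random = "intercept_slope",
           serial = "none")$fixed
}

#' Step 2: explore the variance function
#'
#' Squared OLS residuals of the preliminary mean structure are regressed
#' on time; a significantly increasing variance function selects a
#' random intercept plus slope, otherwise a random intercept only.
#'
#' @param data An [lmm_data()].
#' @param fixed Preliminary fixed terms.
#' @param config A [workflow_config()].
#' @return `"intercept_slope"` or `"intercept"`.
#' @export
explore_variance <- function(data, fixed,
                             config = workflow_config()) {
  stopifnot(inherits(data, "lmm_data"))
  spec <- lmm_spec(fixed = fixed, random = "intercept", serial = "none")
  design <- build_design(data, spec)
  r2 <- lm.fit(design$X, design$y)$residuals^2
  if (nrow(data) < design$p + 3L || length(unique(data$time)) < 3L) {
    warning("too few observations to assess the variance function; ",
            "falling back to a random intercept only")
    return("intercept")
  }
  fit <- lm(r2 ~ data$time)
  sm <- summary(fit)$coefficients
  slope <- sm["data$time", "Estimate"]
  pval <- sm["data$time", "Pr(>|t|)"]
  if (slope > 0 && pval < config$alpha) "intercept_slope" else "intercept"
}

#' Step 3: select the serial-correlation structure
#'
#' Fits the candidate serial structures by REML with the given mean and
#' random structure.  Between Gaussian and exponential the higher REML
#' log-likelihood wins; the winner is retained over "none" only when it
#' improves AIC (two extra parameters).  Non-convergent candidates are
#' recorded and excluded with a warning.
#'
#' @param data An [lmm_data()].
#' @param fixed Fixed terms.
#' @param random Random structure.
#' @param config A [workflow_config()].
#' @return List with `serial` (the choice) and `loglik` (named REML
#'   log-likelihoods of all candidates; `NA` for failures).
#' @export
select_serial <- function(data, fixed, random,
                          config = workflow_config()) {
  cands <- config$serial_candidates
  ll <- setNames(rep(NA_real_, length(cands)), cands)
  fits <- list()
  for (s in cands) {
    spec <- lmm_spec(fixed = fixed, random = random, serial = s)
    f <- tryCatch(reml_fit(data, spec, options = config$fit_options),
                  error = function(e) NULL)
    if (is.null(f)) {
      warning("serial candidate '", s, "' failed to converge; excluded")
      next
    }
    fits[[s]] <- f
    ll[s] <- f$logLik
  }
  if (!is.finite(ll[["none"]])) {
    stop_data("the no-serial reference model failed to converge")
  }
  withserial <- intersect(c("gaussian", "exponential"), names(ll))
  withserial <- withserial[is.finite(ll[withserial])]
  choice <- "none"
  if (length(withserial)) {
    bestser <- withserial[which.max(ll[withserial])]
    # AIC comparison: serial adds tau2 and phi
    if (2 * (ll[[bestser]] - ll[["none"]]) >
        4 + config$serial_aic_margin) {
      choice <- bestser
    }
  }
  list(serial = choice, loglik = ll)
}

#' Step 4: test whether the random slope can be dropped
#'
#' @param data An [lmm_data()].
#' @param spec Current [lmm_spec()] (random structure
#'   `"intercept_slope"`; anything else is returned unchanged).
#' @param config A [workflow_config()].
#' @return List with the possibly reduced `spec`, the mixture-LRT `p`,
#'   and `statistic`.
#' @export
reduce_random_effects <- function(data, spec,
                                  config = workflow_config()) {
  if (spec$random != "intercept_slope") {
    return(list(spec = spec, p = NA_real_, statistic = NA_real_))
  }
  small <- lmm_spec(spec$fixed, random = "intercept",
                    serial = spec$serial)
  f_small <- reml_fit(data, small, options = config$fit_options)
  f_large <- reml_fit(data, spec, options = config$fit_options)
  lrt <- lrt_random_slope(f_small, f_large)
  out_spec <- if (lrt$p >= config$alpha) small else spec
  list(spec = out_spec, p = lrt$p, statistic = lrt$statistic)
}

removable_terms <- function(fixed) {
  out <- character(0)
  for (tm in fixed) {
    blockers <- switch(tm,
      time = c("time2", "time_age"),
      age = c("age2", "age3", "time_age"),
      age2 = "age3",
      character(0)
    )
    if (!length(intersect(blockers, fixed))) out <- c(out, tm)
  }
  out
}

#' Step 5: backward elimination of fixed effects
#'
#' Robust (sandwich) Wald F tests at `alpha`, removing at each step the
#' least significant currently-removable term.  Hierarchy is respected: a
#' main effect is removable only once its higher-order terms and the
#' interaction are gone.  No multiplicity correction is applied (the
#' longitudinal analysis is explorative).  The full elimination path is
#' returned.
#'
#' @param data An [lmm_data()].
#' @param spec Starting [lmm_spec()].
#' @param config A [workflow_config()].
#' @return List with the final `spec`, the final `fit`, and `path` (data
#'   frame of tested terms with F and p at each step).
#' @export
reduce_fixed_effects <- function(data, spec,
                                 config = workflow_config()) {
  path <- list()
  fit <- reml_fit(data, spec, options = config$fit_options)
  repeat {
    cand <- removable_terms(spec$fixed)
    if (!length(cand)) break
    tests <- vapply(cand, function(tm) {
      robust_wald_f(fit, tm)$p
    }, 0)
    worst <- names(tests)[which.max(tests)]
    path[[length(path) + 1L]] <- data.frame(
      term = worst, p = unname(max(tests)),
      removed = max(tests) >= config$alpha, stringsAsFactors = FALSE
    )
    if (max(tests) < config$alpha) break
    spec <- lmm_spec(setdiff(spec$fixed, worst), random = spec$random,
                     serial = spec$serial)
    fit <- reml_fit(data, spec, options = config$fit_options)
  }
  list(spec = spec, fit = fit,
       path = if (length(path)) do.call(rbind, path) else
         data.frame(term = character(0), p = numeric(0),
                    removed = logical(0)))
}

run_workflow_once <- function(data, config) {
  fixed <- explore_mean_structure(data, config)
  random <- explore_variance(data, fixed, config)
  serial_sel <- select_serial(data, fixed, random, config)
  spec <- lmm_spec(fixed, random = random, serial = serial_sel$serial)
  vgram <- if (random == "intercept") {
    tryCatch(semivariogram(data, fixed = fixed), error = function(e) NULL)
  }
  rr <- reduce_random_effects(data, spec, config)
  fe <- reduce_fixed_effects(data, rr$spec, config)
  eb <- empirical_bayes(fe$fit, level = config$outlier_level)
  list(
    preliminary_fixed = fixed, preliminary_random = random,
    serial = serial_sel$serial, serial_loglik = serial_sel$loglik,
    random_slope_lrt = rr[c("statistic", "p")],
    final_random = rr$spec$random,
    elimination_path = fe$path, final_spec = fe$spec, fit = fe$fit,
    variogram = vgram, empirical_bayes = eb,
    outliers = eb$subject[eb$outlier]
  )
}

#' Run the full longitudinal model-building workflow
#'
#' Applies the five-step procedure to each response dataset; when
#' `outlier_removal` is enabled and empirical Bayes flags subjects, the
#' flagged subjects are removed and all five steps are repeated once to
#' define the final model.  Per-response failures are isolated.
#'
#' @param datasets A named list of [lmm_data()] objects (or a single
#'   one).
#' @param config A [workflow_config()].
#' @return Named list of per-response workflow reports (class
#'   `"gait_workflow_report"` each); failed responses carry the error
#'   message in `$error`.
#' @export
run_longitudinal_analysis <- function(datasets,
                                      config = workflow_config()) {
  if (inherits(datasets, "lmm_data")) {
    datasets <- setNames(list(datasets), attr(datasets, "response"))
  }
  if (is.null(names(datasets))) {
    names(datasets) <- vapply(datasets, attr, "", "response")
  }
  reports <- lapply(names(datasets), function(nm) {
    data <- datasets[[nm]]
    res <- tryCatch(
      with_seed(config$seed, {
        rep1 <- run_workflow_once(data, config)
        removed <- character(0)
        if (config$outlier_removal && length(rep1$outliers)) {
          removed <- rep1$outliers
          keep <- !data$subject %in% removed
          data2 <- lmm_data(
            data$subject[keep], data$time[keep],
            data$baseline_age[keep], data$value[keep],
            response = attr(data, "response"),
            units = attr(data, "units"),
            center_age = attr(data, "center_age")
          )
          rep1 <- run_workflow_once(data2, config)
        }
        rep1$removed_subjects <- removed
        rep1$response <- nm
        class(rep1) <- "gait_workflow_report"
        rep1
      }),
      error = function(e) {
        structure(list(response = nm, error = conditionMessage(e)),
                  class = "gait_workflow_report")
      }
    )
    res
  })
  names(reports) <- names(datasets)
  failed <- names(reports)[vapply(reports, function(r) {
    !is.null(r$error)
  }, TRUE)]
  if (length(failed)) {
    warning("workflow failed for response(s): ",
            paste(failed, collapse = ", "))
  }
  reports
}

#' @export
print.gait_workflow_report <- function(x, ...) {
  cat("Workflow report for '", x$response, "'\n", sep = "")
  if (!is.null(x$error)) {
    cat("  FAILED:", x$error, "\n")
    return(invisible(x))
  }
  cat("  preliminary fixed:", paste(x$preliminary_fixed, collapse = ", "),
      "\n  preliminary random:", x$preliminary_random,
      "\n  serial:", x$serial,
      "\n  final random:", x$final_random,
      "\n  final fixed:", paste(x$final_spec$fixed, collapse = ", "),
      "\n  outliers flagged:",
      if (length(x$outliers)) paste(x$outliers, collapse = ", ") else
        "none", "\n")
  invisible(x)
}
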