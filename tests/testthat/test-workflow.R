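# The five-step model-building procedure.

test_that("trend exploration picks the generating polynomial orders", {
  des <- cohort_design(n_subjects = 40L, visits_range = c(4L, 6L))
  # pure linear time trend, low noise -> degree 1 for time
  tr_lin <- toy_truth(c("(Intercept)" = 0, time = 3), sd_int = 0.3,
                      sd_slope = 0, sd_resid = 0.3)
  hits <- vapply(1:10, function(s) {
    d <- simulate_cohort(des, tr_lin, seed = 200 + s)
    fixed <- explore_mean_structure(d)
    !"time2" %in% fixed
  }, TRUE)
  expect_gte(mean(hits), 0.8)

  # cubic baseline-age trend, low noise -> age3 selected
  tr_cub <- toy_truth(c("(Intercept)" = 0, age = 2, age2 = -1,
                        age3 = 0.12),
                      sd_int = 0.3, sd_slope = 0, sd_resid = 0.3)
  hits3 <- vapply(1:10, function(s) {
    d <- simulate_cohort(des, tr_cub, seed = 300 + s)
    "age3" %in% explore_mean_structure(d)
  }, TRUE)
  expect_gte(mean(hits3), 0.8)

  # constant response floors at the a-priori set
  tr0 <- toy_truth(c("(Intercept)" = 5), sd_int = 0.2, sd_slope = 0,
                   sd_resid = 0.2)
  d0 <- simulate_cohort(des, tr0, seed = 41)
  expect_setequal(explore_mean_structure(d0),
                  c("time", "age", "time_age"))
  tiny <- lmm_data(c("a", "a", "b", "b"), c(0, 1, 0, 1),
                   c(5, 5, 6, 6), 1:4)
  expect_error(explore_mean_structure(tiny), "10 distinct")
})

test_that("the variance function selects the random structure", {
  des <- cohort_design(n_subjects = 40L, visits_range = c(4L, 6L))
  tr_slope <- toy_truth(c("(Intercept)" = 0, time = 0), sd_int = 0.5,
                        sd_slope = 2, sd_resid = 0.5)
  picks <- vapply(1:20, function(s) {
    d <- simulate_cohort(des, tr_slope, seed = 500 + s)
    explore_variance(d, c("time", "age", "time_age"))
  }, "")
  expect_gte(mean(picks == "intercept_slope"), 0.9)

  tr_flat <- toy_truth(c("(Intercept)" = 0, time = 0), sd_int = 1,
                       sd_slope = 0, sd_resid = 1)
  picks0 <- vapply(1:20, function(s) {
    d <- simulate_cohort(des, tr_flat, seed = 600 + s)
    explore_variance(d, c("time", "age", "time_age"))
  }, "")
  expect_gte(mean(picks0 == "intercept"), 0.9)

  tiny <- lmm_data(c("a", "b"), c(0, 0), c(5, 6), c(1, 2))
  expect_warning(out <- explore_variance(tiny, character(0)),
                 "falling back")
  expect_identical(out, "intercept")
})

test_that("serial selection prefers the generating structure", {
  des <- cohort_design(n_subjects = 30L, visits_range = c(4L, 7L))
  cfg <- workflow_config(fit_options = fast_opts)
  # no serial component: "none" wins the AIC comparison mostly
  tr0 <- toy_truth(c("(Intercept)" = 0, time = 0.5), sd_int = 1,
                   sd_slope = 0, sd_resid = 0.7)
  picks <- vapply(1:7, function(s) {
    d <- simulate_cohort(des, tr0, seed = 700 + s)
    sel <- select_serial(d, "time", "intercept", cfg)
    expect_length(sel$loglik, 3L)
    sel$serial
  }, "")
  expect_gte(mean(picks == "none"), 0.5)

  # strong exponential serial correlation: a serial structure is
  # retained in the clear majority.  Exponential and Gaussian with a
  # free measurement-error nugget are near-equivalent families at
  # cohort scale (log-likelihood gaps of a few units at most), so the
  # test asserts detection of serial correlation and that
  # near-equivalence, not the form choice itself.
  trS <- toy_truth(c("(Intercept)" = 0, time = 0.5), sd_int = 0.5,
                   sd_slope = 0, sd_resid = 0.3, serial = "exponential",
                   tau2 = 2.5, phi = 1.2)
  sels <- lapply(1:10, function(s) {
    d <- simulate_cohort(des, trS, seed = 800 + s)
    select_serial(d, "time", "intercept", cfg)
  })
  picksS <- vapply(sels, `[[`, "", "serial")
  expect_gte(mean(picksS != "none"), 0.7)
  gaps <- vapply(sels, function(sl) {
    abs(sl$loglik[["gaussian"]] - sl$loglik[["exponential"]])
  }, 0)
  expect_lt(median(gaps), 3)
})

test_that("random-slope reduction keeps real slopes, drops null ones", {
  cfg <- workflow_config(fit_options = fast_opts)
  des <- cohort_design(n_subjects = 25L, visits_range = c(3L, 6L))
  tr_big <- toy_truth(c("(Intercept)" = 0, time = 1), sd_int = 1,
                      sd_slope = 2, sd_resid = 0.4)
  kept <- vapply(1:10, function(s) {
    d <- simulate_cohort(des, tr_big, seed = 900 + s)
    sp <- lmm_spec("time", random = "intercept_slope")
    reduce_random_effects(d, sp, cfg)$spec$random == "intercept_slope"
  }, TRUE)
  expect_gte(mean(kept), 0.9)
  # intercept-only input returned unchanged
  sp0 <- lmm_spec("time", random = "intercept")
  d <- simulate_cohort(des, tr_big, seed = 1)
  expect_identical(reduce_random_effects(d, sp0, cfg)$spec, sp0)
})

test_that("fixed-effect elimination respects hierarchy and signal", {
  cfg <- workflow_config(fit_options = fast_opts)
  des <- cohort_design(n_subjects = 30L, visits_range = c(3L, 6L))
  # truth {intercept, time}: higher-order terms get eliminated
  tr <- toy_truth(c("(Intercept)" = 5, time = 2), sd_int = 0.8,
                  sd_slope = 0.3, sd_resid = 0.4)
  keeps <- vapply(1:8, function(s) {
    d <- simulate_cohort(des, tr, seed = 1000 + s)
    res <- reduce_fixed_effects(
      d, lmm_spec(c("time", "time2", "age", "time_age")), cfg
    )
    ("time" %in% res$spec$fixed) && !("time2" %in% res$spec$fixed)
  }, TRUE)
  expect_gte(mean(keeps), 0.7)

  # with the interaction present, mains are never candidates
  d <- simulate_cohort(des, tr, seed = 1)
  expect_setequal(
    gaitlong:::removable_terms(c("time", "age", "time_age")), "time_age"
  )
  expect_setequal(
    gaitlong:::removable_terms(c("time", "age", "age2", "age3")),
    c("time", "age3")
  )

  # all terms strongly significant: nothing removed
  tr_all <- toy_truth(c("(Intercept)" = 0, time = 3, age = 3,
                        time_age = 1.5),
                      sd_int = 0.4, sd_slope = 0.2, sd_resid = 0.3)
  d2 <- simulate_cohort(des, tr_all, seed = 77)
  res2 <- reduce_fixed_effects(d2, lmm_spec(c("time", "age", "time_age")),
                               cfg)
  expect_setequal(res2$spec$fixed, c("time", "age", "time_age"))
})

test_that("the batch driver isolates failures and is deterministic", {
  tr1 <- default_truth_sets()$cadence
  tr2 <- default_truth_sets()$dorsiflex_ic
  d1 <- simulate_cohort(cohort_design(), tr1, seed = 21)
  d2 <- simulate_cohort(cohort_design(), tr2, seed = 22)
  broken <- lmm_data(c("a", "b"), c(0, 0), c(5, 6), c(1, 2),
                     response = "broken")
  cfg <- workflow_config(fit_options = fast_opts, seed = 9L)
  reports <- suppressWarnings(
    run_longitudinal_analysis(list(cadence = d1, broken = broken,
                                   dorsiflex_ic = d2), cfg)
  )
  expect_named(reports, c("cadence", "broken", "dorsiflex_ic"))
  expect_null(reports$cadence$error)
  expect_false(is.null(reports$broken$error))
  expect_true(reports$cadence$fit$convergence$code)
  expect_true(reports$cadence$final_spec$random %in%
                c("intercept", "intercept_slope"))
  # hierarchy always holds in the final spec
  expect_silent(do.call(lmm_spec, list(
    fixed = reports$cadence$final_spec$fixed,
    random = reports$cadence$final_spec$random,
    serial = reports$cadence$final_spec$serial
  )))

  # byte-identical reports under the same config and seed
  again <- suppressWarnings(
    run_longitudinal_analysis(list(cadence = d1), cfg)
  )
  expect_identical(serialize(reports$cadence, NULL, version = 3),
                   serialize(again$cadence, NULL, version = 3))

  # no subject is dropped when outlier removal is off
  expect_length(reports$cadence$removed_subjects, 0L)

  tab <- render_fixed_effects_table(reports)
  expect_equal(nrow(tab), 3L)
  expect_true(any(grepl("\\*", unlist(tab[tab$response == "cadence",
                                          -(1:2)]))))
})
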