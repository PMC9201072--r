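# Sandwich covariance, robust Wald F, boundary LRT, empirical Bayes,
# prediction, semi-variogram.

test_that("sandwich reduces to HC0 when V = sigma2 I, one obs/subject", {
  with_seed(21, {
    n <- 60L
    X <- cbind(1, rnorm(n), runif(n))
    colnames(X) <- c("(Intercept)", "x1", "x2")
    y <- X %*% c(1, 2, -1) + rnorm(n) * (1 + abs(X[, 2]))
    beta <- solve(crossprod(X), crossprod(X, y))
    blocks <- lapply(seq_len(n), function(i) {
      list(X = X[i, , drop = FALSE], Z = matrix(1, 1, 1), y = y[i],
           times = 0, subject = as.character(i), idx = i)
    })
    names(blocks) <- as.character(seq_len(n))
    fit <- structure(list(
      beta = setNames(as.numeric(beta), colnames(X)),
      G = matrix(0, 1, 1), sigma2 = 1.7, tau2 = 0, phi = NA,
      serial = "none", p = 3L, n_subjects = n,
      vcov_model = diag(3),
      design = list(blocks = blocks)
    ), class = "lmm_fit")
    got <- sandwich_covariance(fit)
    r <- as.numeric(y - X %*% beta)
    XtXi <- solve(crossprod(X))
    hc0 <- XtXi %*% t(X) %*% diag(r^2) %*% X %*% XtXi
    expect_equal(unname(got), unname(hc0), tolerance = 1e-10)
  })
})

test_that("robust and model-based covariances agree under correct spec", {
  truth <- toy_truth(c("(Intercept)" = 3, time = 0.4), sd_int = 1,
                     sd_slope = 0.3, sd_resid = 0.5)
  d <- simulate_cohort(cohort_design(n_subjects = 150L,
                                     visits_range = c(3L, 6L)),
                       truth, seed = 77)
  f <- reml_fit(d, lmm_spec("time"), options = fast_opts)
  rob <- sandwich_covariance(f)
  expect_equal(rob, t(rob))
  expect_true(all(eigen(rob, symmetric = TRUE,
                        only.values = TRUE)$values >= 0))
  ratio <- sqrt(diag(rob)) / sqrt(diag(f$vcov_model))
  expect_true(all(ratio > 0.75 & ratio < 1.3))
})

test_that("robust Wald F behaves like its algebra says", {
  truth <- toy_truth(c("(Intercept)" = 3, time = 0.4), sd_int = 1,
                     sd_slope = 0.2, sd_resid = 0.5)
  d <- simulate_cohort(small_design(25L), truth, seed = 5)
  f <- reml_fit(d, lmm_spec("time"), options = fast_opts)
  # single row: F = t^2 built from the same covariance
  w <- robust_wald_f(f, "time")
  S <- sandwich_covariance(f)
  tstat <- f$beta[["time"]] / sqrt(S["time", "time"])
  expect_equal(w$F, tstat^2, tolerance = 1e-10)
  expect_equal(w$df1, 1L)
  expect_equal(w$df2, f$n_subjects - f$p)
  # a contrast annihilating beta gives F = 0, p = 1
  L <- matrix(c(-f$beta[["time"]] / f$beta[["(Intercept)"]], 1), 1)
  expect_equal(robust_wald_f(f, c(L))$F, 0, tolerance = 1e-12)
  expect_equal(robust_wald_f(f, c(L))$p, 1)
  expect_error(robust_wald_f(f, rbind(c(1, 0), c(2, 0))),
               "linearly dependent")
  expect_error(robust_wald_f(f, "nosuch"), "unknown coefficient")
})

test_that("robust F holds its level approximately under a true null", {
  # time coefficient truly zero; moderate cohort; level within
  # Monte-Carlo + small-sample slack of the nominal 5%
  truth <- toy_truth(c("(Intercept)" = 2), sd_int = 1, sd_slope = 0,
                     sd_resid = 0.7)
  des <- cohort_design(n_subjects = 40L, visits_range = c(3L, 5L))
  rej <- vapply(1:200, function(s) {
    d <- simulate_cohort(des, truth, seed = 9000 + s)
    f <- reml_fit(d, lmm_spec("time", random = "intercept"),
                  options = list(n_restarts = 0))
    robust_wald_f(f, "time")$p < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.015)
  expect_lte(mean(rej), 0.11)
})

test_that("the mixture chi-square LRT has the stated tails and level", {
  # T = 0 -> p = 1 exactly
  truth <- toy_truth(c("(Intercept)" = 2, time = 0.3), sd_int = 1,
                     sd_slope = 0, sd_resid = 0.7)
  d <- simulate_cohort(small_design(), truth, seed = 3)
  fs <- reml_fit(d, lmm_spec("time", random = "intercept"),
                 options = fast_opts)
  fl <- reml_fit(d, lmm_spec("time", random = "intercept_slope"),
                 options = fast_opts)
  lrt <- lrt_random_slope(fs, fl)
  expect_gte(lrt$statistic, 0)
  if (lrt$statistic == 0) expect_equal(lrt$p, 1)
  # chi-square table value at T = 3.84: p = (0.0500 + 0.1466)/2
  p384 <- 0.5 * pchisq(3.84, 1, lower.tail = FALSE) +
    0.5 * pchisq(3.84, 2, lower.tail = FALSE)
  expect_equal(round(p384, 4), 0.0983)
  expect_error(
    lrt_random_slope(
      reml_fit(d, lmm_spec(c("time", "age"), random = "intercept"),
               options = fast_opts), fl),
    "mean structures"
  )
})

test_that("the boundary LRT holds its level with zero slope variance", {
  truth <- toy_truth(c("(Intercept)" = 2, time = 0.3), sd_int = 1,
                     sd_slope = 0, sd_resid = 0.7)
  des <- small_design()
  pvals <- vapply(1:200, function(s) {
    d <- simulate_cohort(des, truth, seed = 4000 + s)
    fs <- reml_fit(d, lmm_spec("time", random = "intercept"),
                   options = list(n_restarts = 0))
    fl <- reml_fit(d, lmm_spec("time", random = "intercept_slope"),
                   options = list(n_restarts = 0))
    lrt_random_slope(fs, fl)$p
  }, 0)
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.10)
})

test_that("empirical Bayes shrinks, zeroes on zero residuals, flags", {
  truth <- toy_truth(c("(Intercept)" = 0, time = 0), sd_int = 2,
                     sd_slope = 0.5, sd_resid = 0.5)
  d <- simulate_cohort(cohort_design(n_subjects = 60L,
                                     visits_range = c(3L, 6L)),
                       truth, seed = 13)
  f <- reml_fit(d, lmm_spec("time"), options = fast_opts)
  eb <- empirical_bayes(f)
  # predictions centre near zero across many subjects
  expect_lt(abs(mean(eb$intercept)), 3 * sd(eb$intercept) / sqrt(60))
  expect_lt(abs(mean(eb$slope)), 3 * sd(eb$slope) / sqrt(60))

  # zero residuals give exactly zero predictions
  f0 <- f
  f0$design$blocks <- lapply(f0$design$blocks, function(b) {
    b$y <- as.numeric(b$X %*% f$beta)
    b
  })
  eb0 <- empirical_bayes(f0)
  expect_equal(max(abs(c(eb0$intercept, eb0$slope, eb0$distance))), 0)

  # a subject displaced by 10 intercept SDs is flagged at the 0.99 level
  d2 <- d
  shift <- d2$subject == d2$subject[1]
  d2$value[shift] <- d2$value[shift] + 10 * 2
  d2 <- lmm_data(d2$subject, d2$time, d2$baseline_age, d2$value,
                 center_age = attr(d, "center_age"))
  f2 <- reml_fit(d2, lmm_spec("time"), options = fast_opts)
  eb2 <- empirical_bayes(f2, level = 0.99)
  expect_true(eb2$outlier[eb2$subject == d2$subject[1]])
})

test_that("profile predictions follow the fitted surfaces", {
  truth <- default_truth_sets()$sw_norm
  d <- simulate_cohort(cohort_design(), truth, seed = 8)
  f <- reml_fit(d, truth_spec(truth), options = fast_opts)
  # population prediction at time 0, minimum baseline age = intercept
  p0 <- predict_profile(
    f, data.frame(time = 0, baseline_age = attr(d, "center_age"))
  )
  expect_equal(p0, f$beta[["(Intercept)"]])
  # population and subject curves coincide when b_i = 0
  f0 <- f
  f0$design$blocks <- lapply(f0$design$blocks, function(b) {
    b$y <- as.numeric(b$X %*% f$beta)
    b
  })
  nd <- data.frame(subject = d$subject[1:3], time = c(0, 1, 2),
                   baseline_age = d$baseline_age[1:3])
  expect_equal(predict_profile(f0, nd, include_random = TRUE),
               predict_profile(f0, nd, include_random = FALSE))
  # linear in time when time2 is excluded
  tr2 <- toy_truth(c("(Intercept)" = 1, time = 2), sd_resid = 0.4)
  d2 <- simulate_cohort(small_design(), tr2, seed = 2)
  f2 <- reml_fit(d2, lmm_spec("time"), options = fast_opts)
  tt <- 0:4
  pr <- predict_profile(f2, data.frame(time = tt, baseline_age =
                                         attr(d2, "center_age")))
  expect_equal(diff(pr), rep(diff(pr)[1], 4), tolerance = 1e-10)
  expect_error(
    predict_profile(f, data.frame(subject = "ghost", time = 0,
                                  baseline_age = 5),
                    include_random = TRUE),
    "not in the fitting data"
  )
})

test_that("the semi-variogram separates iid noise from serial wear-in", {
  # iid noise: smoothed variogram flat near sigma2 at all lags
  truth <- toy_truth(c("(Intercept)" = 0), sd_int = 1, sd_slope = 0,
                     sd_resid = 1)
  d <- simulate_cohort(cohort_design(n_subjects = 80L,
                                     visits_range = c(4L, 7L)),
                       truth, seed = 19)
  v <- semivariogram(d, fixed = "time")
  g <- v$smoothed$gamma[is.finite(v$smoothed$gamma)]
  expect_true(all(abs(g - 1) < 0.45))
  expect_true(all(v$pairs$v >= 0))
  expect_true(all(v$pairs$u > 0))

  # equal residuals contribute v = 0 pairs
  d0 <- lmm_data(rep(c("a", "b"), each = 2), c(0, 1, 0, 1),
                 c(5, 5, 6, 6), c(1, 1, 2, 2))
  v0 <- semivariogram(d0, fixed = character(0))
  expect_true(any(v0$pairs$v < 1e-20))

  # strong exponential serial component: increasing trend in lag
  truthS <- toy_truth(c("(Intercept)" = 0), sd_int = 0.3, sd_slope = 0,
                      sd_resid = 0.3, serial = "exponential",
                      tau2 = 2, phi = 1.5)
  dS <- simulate_cohort(cohort_design(n_subjects = 80L,
                                      visits_range = c(4L, 7L)),
                        truthS, seed = 23)
  vS <- semivariogram(dS, fixed = "time")
  sm <- vS$smoothed[is.finite(vS$smoothed$gamma), ]
  iso <- isoreg(sm$lag, sm$gamma)
  # the isotonic fit explains most of the variation around the mean
  ss_tot <- sum((sm$gamma - mean(sm$gamma))^2)
  ss_res <- sum((iso$yf - sm$gamma)^2)
  expect_lt(ss_res, 0.4 * ss_tot)
  expect_gt(tail(iso$yf, 1), head(iso$yf, 1))
  expect_error(semivariogram(lmm_data(c("a", "b"), c(0, 0), c(5, 6),
                                      c(1, 2)), fixed = character(0)),
               "two or more")
})
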