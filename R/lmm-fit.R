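# REML estimation of the marginal linear mixed model
#
#   y_i ~ N(X_i beta, V_i),
#   V_i = Z_i G Z_i' + sigma2 I + tau2 H_i(phi),
#
# with H_i[j,k] = exp(-u/phi) (exponential) or exp(-(u/phi)^2) (Gaussian)
# for within-subject lags u = |t_j - t_k|.  The restricted likelihood is
# profiled over beta (GLS) and over an overall scale sigma2, leaving a
# low-dimensional optimisation over variance ratios: the random-effect
# covariance relative to sigma2 (via its Cholesky factor) and, when a
# serial component is present, the serial variance ratio and range.
# Boundary-prone surfaces are handled by log parameterisation and
# seeded multi-start optimisation.

#' Serial correlation function
#'
#' @param u Non-negative time lags (years).
#' @param serial `"gaussian"` or `"exponential"`.
#' @param phi Range parameter, > 0.
#' @return Correlations in (0, 1]; `u = 0` maps to exactly 1.
#' @export
serial_correlation <- function(u, serial, phi) {
  if (!is.finite(phi) || phi <= 0) {
    stop_data("serial range phi must be positive")
  }
  switch(serial,
    exponential = exp(-u / phi),
    gaussian = exp(-(u / phi)^2),
    stop_spec("unknown serial structure '", serial, "'")
  )
}

#' Marginal covariance matrix of one subject
#'
#' `V = Z G Z' + sigma2 I + tau2 H(phi)` evaluated at the subject's
#' measurement times, with `Z = [1]` or `[1, t]` according to the
#' dimension of `G`.
#'
#' @param times Measurement times (years).
#' @param params List with `G` (1x1 or 2x2 matrix), `sigma2` (> 0),
#'   `serial` (`"none"`, `"gaussian"`, `"exponential"`), and for serial
#'   structures `tau2` (>= 0) and `phi` (> 0).
#' @return The marginal covariance matrix.
#' @export
marginal_covariance <- function(times, params) {
  G <- as.matrix(params$G)
  q <- nrow(G)
  stopifnot(q %in% 1:2, isTRUE(all.equal(G, t(G))))
  if (!is.finite(params$sigma2) || params$sigma2 <= 0) {
    stop_data("sigma2 must be positive")
  }
  n <- length(times)
  Z <- if (q == 2L) cbind(1, times) else matrix(1, n, 1L)
  V <- Z %*% G %*% t(Z) + diag(params$sigma2, n)
  serial <- if (is.null(params$serial)) "none" else params$serial
  if (serial != "none") {
    tau2 <- params$tau2
    if (!is.finite(tau2) || tau2 < 0) stop_data("tau2 must be >= 0")
    U <- abs(outer(times, times, "-"))
    V <- V + tau2 * serial_correlation(U, serial, params$phi)
  }
  (V + t(V)) / 2
}

# --- internal objective ---------------------------------------------------

# theta layout:
#   random intercept:        theta[1] = log L11            (G* = L L')
#   intercept+slope:         theta[1:3] = log L11, log L22, L21
#   serial != none: append   log(tau2/sigma2), log(phi)
theta_template <- function(spec) {
  nm <- if (spec$random == "intercept_slope") {
    c("log_l11", "log_l22", "l21")
  } else "log_l11"
  if (spec$serial != "none") nm <- c(nm, "log_tau2r", "log_phi")
  nm
}

theta_to_params <- function(theta, spec) {
  th <- pmin(pmax(theta, -25), 25)
  if (spec$random == "intercept_slope") {
    L <- matrix(c(exp(th[1L]), th[3L], 0, exp(th[2L])), 2L, 2L)
    k <- 3L
  } else {
    L <- matrix(exp(th[1L]), 1L, 1L)
    k <- 1L
  }
  Gs <- L %*% t(L)
  if (spec$serial != "none") {
    list(Gstar = Gs, tau2r = exp(th[k + 1L]), phi = exp(th[k + 2L]))
  } else {
    list(Gstar = Gs, tau2r = 0, phi = NA_real_)
  }
}

# Precompute per-subject cross-products for the serial-free fast path.
precompute_blocks <- function(design) {
  lapply(design$blocks, function(b) {
    XY <- cbind(b$X, b$y)
    list(
      Axy = crossprod(XY), Czx = crossprod(b$Z, XY),
      Czz = crossprod(b$Z), n = length(b$y)
    )
  })
}

# -2 x profiled restricted log-likelihood (profiled over beta and sigma2).
# Returns a large value on numerical failure so optimisers step back.
reml_objective <- function(theta, design, pre, spec) {
  pars <- theta_to_params(theta, spec)
  p <- design$p
  N <- design$n
  S <- matrix(0, p + 1L, p + 1L)
  logdet_w <- 0
  ok <- TRUE
  if (spec$serial == "none") {
    Gs <- pars$Gstar
    q <- nrow(Gs)
    for (b in pre) {
      T_ <- diag(q) + b$Czz %*% Gs
      dt <- det(T_)
      if (!is.finite(dt) || dt <= 0) { ok <- FALSE; break }
      A <- Gs %*% solve(T_)
      S <- S + b$Axy - crossprod(b$Czx, A %*% b$Czx)
      logdet_w <- logdet_w + log(dt)
    }
  } else {
    for (b in design$blocks) {
      n_i <- length(b$y)
      U <- abs(outer(b$times, b$times, "-"))
      W <- b$Z %*% pars$Gstar %*% t(b$Z) + diag(n_i) +
        pars$tau2r * serial_correlation(U, spec$serial, pars$phi)
      ch <- tryCatch(chol(W), error = function(e) NULL)
      if (is.null(ch)) { ok <- FALSE; break }
      half <- backsolve(ch, cbind(b$X, b$y), transpose = TRUE)
      S <- S + crossprod(half)
      logdet_w <- logdet_w + 2 * sum(log(diag(ch)))
    }
  }
  if (!ok) return(1e10)
  Sxx <- S[seq_len(p), seq_len(p), drop = FALSE]
  sxy <- S[seq_len(p), p + 1L]
  syy <- S[p + 1L, p + 1L]
  chx <- tryCatch(chol(Sxx), error = function(e) NULL)
  if (is.null(chx)) return(1e10)
  beta <- backsolve(chx, backsolve(chx, sxy, transpose = TRUE))
  Q <- syy - sum(sxy * beta)
  if (!is.finite(Q) || Q <= 0) return(1e10)
  val <- (N - p) * (log(2 * pi) + 1 + log(Q / (N - p))) +
    logdet_w + 2 * sum(log(diag(chx)))
  if (!is.finite(val)) return(1e10)
  val
}

moment_start <- function(design, spec) {
  # OLS residual moments give a crude split of between- and
  # within-subject variance for the optimiser's deterministic start.
  fit <- lm.fit(design$X, design$y)
  r <- fit$residuals
  subj <- rep(seq_along(design$blocks),
              vapply(design$blocks, function(b) length(b$y), 1L))
  m <- tapply(r, subj, mean)
  wi <- tapply(r, subj, function(x) {
    if (length(x) >= 2) var(x) else NA_real_
  })
  vw <- mean(wi, na.rm = TRUE)
  if (!is.finite(vw) || vw <= 0) vw <- var(r) / 2
  nbar <- mean(vapply(design$blocks, function(b) length(b$y), 1L))
  vb <- max(var(as.numeric(m)) - vw / nbar, 0.05 * vw)
  g11 <- vb / vw
  th <- 0.5 * log(g11)
  if (spec$random == "intercept_slope") {
    th <- c(th, 0.5 * log(g11) + log(0.3), 0)
  }
  if (spec$serial != "none") {
    lags <- unlist(lapply(design$blocks, function(b) {
      u <- abs(outer(b$times, b$times, "-"))
      u[upper.tri(u)]
    }))
    phi0 <- median(lags[lags > 0])
    if (!is.finite(phi0) || phi0 <= 0) phi0 <- 1
    th <- c(th, log(0.5), log(phi0))
  }
  th
}

#' Fit the linear mixed model by restricted maximum likelihood
#'
#' Variance parameters maximise the restricted likelihood (profiled over
#' the fixed effects by generalised least squares and over the
#' measurement-error variance); the fixed effects are the GLS estimate at
#' the optimum.  Optimisation is over log-transformed variance ratios and
#' the Cholesky factor of the random-effect covariance, from a
#' moment-based start plus seeded random restarts.
#'
#' @param data An [lmm_data()].
#' @param spec An [lmm_spec()].
#' @param options List: `n_restarts` (random restarts beyond the
#'   moment-based start, default 5), `seed` (restart seed, default 1),
#'   `maxit`, `reltol` (optimiser control).
#' @return An object of class `"lmm_fit"`: `beta`, `G`, `sigma2`, `tau2`,
#'   `phi`, model-based covariance of `beta`, REML log-likelihood, and
#'   convergence diagnostics.  Failure to converge on every start raises
#'   an error carrying the diagnostics.
#' @export
reml_fit <- function(data, spec, options = list()) {
  opts <- list(n_restarts = 5L, seed = 1L, maxit = 2000L, reltol = 1e-10)
  opts[names(options)] <- options
  design <- build_design(data, spec)
  if (length(design$blocks) < 2L) stop_data("need at least 2 subjects")
  if (design$n <= design$p) {
    stop_data("more fixed-effect terms than observations")
  }
  if (qr(design$X)$rank < design$p) {
    stop_data("singular fixed-effect design matrix")
  }
  pre <- if (spec$serial == "none") precompute_blocks(design) else NULL

  th0 <- moment_start(design, spec)
  starts <- list(th0)
  if (opts$n_restarts > 0) {
    pert <- with_seed(opts$seed, {
      lapply(seq_len(opts$n_restarts), function(i) {
        th0 + rnorm(length(th0), sd = 1)
      })
    })
    starts <- c(starts, pert)
  }

  fits <- lapply(starts, function(th) {
    if (length(th) == 1L) {
      o <- optimise(function(t1) reml_objective(t1, design, pre, spec),
                    interval = c(-15, 10))
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      o <- optim(th, reml_objective, design = design, pre = pre,
                 spec = spec, method = "Nelder-Mead",
                 control = list(maxit = opts$maxit,
                                reltol = opts$reltol))
      o[c("par", "value", "convergence")]
    }
  })
  vals <- vapply(fits, `[[`, 0, "value")
  if (all(vals >= 1e10)) {
    stop(structure(
      class = c("gaitlong_convergence_error", "error", "condition"),
      list(message = "REML optimisation failed on every start",
           call = sys.call(), diagnostics = fits)
    ))
  }
  best <- fits[[which.min(vals)]]
  theta <- setNames(best$par, theta_template(spec))
  pars <- theta_to_params(theta, spec)

  # final pass: recover beta, sigma2, covariance of beta
  p <- design$p
  N <- design$n
  S <- matrix(0, p + 1L, p + 1L)
  for (b in design$blocks) {
    n_i <- length(b$y)
    W <- b$Z %*% pars$Gstar %*% t(b$Z) + diag(n_i)
    if (spec$serial != "none") {
      U <- abs(outer(b$times, b$times, "-"))
      W <- W + pars$tau2r * serial_correlation(U, spec$serial, pars$phi)
    }
    half <- backsolve(chol(W), cbind(b$X, b$y), transpose = TRUE)
    S <- S + crossprod(half)
  }
  Sxx <- S[seq_len(p), seq_len(p), drop = FALSE]
  sxy <- S[seq_len(p), p + 1L]
  beta <- solve(Sxx, sxy)
  sigma2 <- (S[p + 1L, p + 1L] - sum(sxy * beta)) / (N - p)
  G <- pars$Gstar * sigma2
  dimnames(G) <- NULL
  vcov_model <- sigma2 * solve(Sxx)
  cols <- colnames(design$X)
  beta <- setNames(as.numeric(beta), cols)
  dimnames(vcov_model) <- list(cols, cols)
  loglik <- -0.5 * best$value

  fitted <- as.numeric(design$X %*% beta)
  out <- structure(
    list(
      beta = beta, G = G, sigma2 = sigma2,
      tau2 = pars$tau2r * sigma2,
      phi = if (spec$serial != "none") pars$phi else NA_real_,
      serial = spec$serial, spec = spec, theta = theta,
      logLik = loglik, vcov_model = vcov_model,
      fitted = fitted, residuals = design$y - fitted,
      data = data, design = design,
      N = N, p = p, n_subjects = length(design$blocks),
      convergence = list(
        code = best$value < 1e10 && (is.null(best$convergence) ||
                                       best$convergence == 0L),
        optim_code = best$convergence,
        objective = best$value,
        start_values = vals
      )
    ),
    class = "lmm_fit"
  )
  if (!out$convergence$code) {
    warning("REML fit did not converge cleanly; inspect $convergence")
  }
  out
}

# Marginal covariance blocks of a fitted model (response scale).
fit_v_blocks <- function(fit) {
  lapply(fit$design$blocks, function(b) {
    marginal_covariance(b$times, list(
      G = matrix_q(fit), sigma2 = fit$sigma2, tau2 = fit$tau2,
      phi = fit$phi, serial = fit$serial
    ))
  })
}

matrix_q <- function(fit) as.matrix(fit$G)

#' @export
print.lmm_fit <- function(x, digits = 4, ...) {
  cat("Linear mixed model (REML) for '",
      attr(x$data, "response"), "'\n", sep = "")
  cat("  fixed:", paste(names(x$beta), collapse = ", "), "\n")
  cat("  random:", x$spec$random, " serial:", x$serial, "\n")
  est <- cbind(estimate = x$beta,
               se = sqrt(diag(x$vcov_model)))
  print(round(est, digits))
  cat("  sigma2 =", signif(x$sigma2, digits))
  cat("  G diag =", paste(signif(diag(as.matrix(x$G)), digits),
                          collapse = ", "))
  if (x$serial != "none") {
    cat("  tau2 =", signif(x$tau2, digits),
        " phi =", signif(x$phi, digits))
  }
  cat("\n  REML logLik =", round(x$logLik, 3),
      " converged:", x$convergence$code, "\n")
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...) object$beta

#' @export
logLik.lmm_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$beta) +
              length(object$theta) + 1, class = "logLik")
}

#' Covariance of the fixed effects
#'
#' @param object An `lmm_fit`.
#' @param type `"model"` for the model-based (inverse information) form,
#'   `"robust"` for the sandwich estimate.
#' @param ... Unused.
#' @export
vcov.lmm_fit <- function(object, type = c("model", "robust"), ...) {
  type <- match.arg(type)
  if (type == "model") object$vcov_model else sandwich_covariance(object)
}
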