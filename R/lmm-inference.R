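# Inference around a fitted marginal mixed model: sandwich-robust
# covariance and Wald F tests, the boundary likelihood ratio test for the
# random slope, empirical Bayes prediction of subject-level effects with
# outlier screening, profile prediction, and the semi-variogram serial
# correlation diagnostic.

#' Sandwich (robust) covariance of the fixed effects
#'
#' `A^{-1} B A^{-1}` with `A = sum_i X_i' V_i^{-1} X_i` and
#' `B = sum_i X_i' V_i^{-1} r_i r_i' V_i^{-1} X_i`, `r_i` the marginal
#' residuals.  Consistent for the covariance of the GLS fixed effects
#' even when the covariance model is misspecified.
#'
#' @param fit An [reml_fit()] result.
#' @return Symmetric positive semidefinite matrix.
#' @export
sandwich_covariance <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  p <- fit$p
  A <- matrix(0, p, p)
  B <- matrix(0, p, p)
  Vs <- fit_v_blocks(fit)
  for (k in seq_along(fit$design$blocks)) {
    b <- fit$design$blocks[[k]]
    ch <- chol(Vs[[k]])
    Xi <- backsolve(ch, b$X, transpose = TRUE)      # V^{-1/2} X
    ri <- backsolve(ch, b$y - b$X %*% fit$beta, transpose = TRUE)
    A <- A + crossprod(Xi)
    u <- crossprod(Xi, ri)                          # X' V^{-1} r
    B <- B + tcrossprod(u)
  }
  Ainv <- tryCatch(solve(A), error = function(e) {
    stop_data("sandwich: X' V^{-1} X is singular")
  })
  out <- Ainv %*% B %*% Ainv
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(fit$vcov_model)
  out
}

#' Robust Wald F test of fixed-effect contrasts
#'
#' Wald statistic `(L b)' (L S L')^{-1} (L b) / r` with `S` the sandwich
#' covariance (by default) and `r = rank(L)`, referred to an F
#' distribution with denominator degrees of freedom `n_subjects - p`
#' (between-within convention; configurable).
#'
#' @param fit An [reml_fit()] result.
#' @param L Contrast matrix (rows = contrasts) or a single contrast
#'   vector, or a character vector of coefficient names to test jointly
#'   against zero.
#' @param vcov_type `"robust"` (default) or `"model"`.
#' @param ddf Denominator degrees of freedom override.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
robust_wald_f <- function(fit, L, vcov_type = c("robust", "model"),
                          ddf = NULL) {
  stopifnot(inherits(fit, "lmm_fit"))
  vcov_type <- match.arg(vcov_type)
  p <- fit$p
  if (is.character(L)) {
    miss <- setdiff(L, names(fit$beta))
    if (length(miss)) {
      stop_data("unknown coefficient(s): ", paste(miss, collapse = ", "))
    }
    M <- matrix(0, length(L), p, dimnames = list(L, names(fit$beta)))
    for (nm in L) M[nm, nm] <- 1
    L <- M
  }
  if (is.null(dim(L))) L <- matrix(L, nrow = 1L)
  if (ncol(L) != p) stop_data("contrast has ", ncol(L),
                              " columns; expected ", p)
  r <- qr(L)$rank
  if (r < nrow(L)) stop_data("contrast rows are linearly dependent")
  S <- if (vcov_type == "robust") sandwich_covariance(fit) else
    fit$vcov_model
  Lb <- L %*% fit$beta
  M <- L %*% S %*% t(L)
  Fstat <- as.numeric(crossprod(Lb, solve(M, Lb))) / r
  if (is.null(ddf)) ddf <- fit$n_subjects - p
  if (ddf <= 0) stop_data("non-positive denominator df")
  list(F = Fstat, df1 = r, df2 = ddf,
       p = pf(Fstat, r, ddf, lower.tail = FALSE))
}

#' Boundary likelihood ratio test for the random slope
#'
#' Compares a random-intercept model against a random-intercept-plus-
#' slope model with the same mean and serial structure.  Because the
#' slope variance sits on the boundary of the parameter space, the LRT
#' statistic is referred to an equal-weight mixture of chi-square
#' distributions with 1 and 2 degrees of freedom.
#'
#' @param fit_small Random-intercept fit.
#' @param fit_large Random-intercept-plus-slope fit.
#' @return List with `statistic` (clipped at 0) and `p`.
#' @export
lrt_random_slope <- function(fit_small, fit_large) {
  stopifnot(inherits(fit_small, "lmm_fit"), inherits(fit_large, "lmm_fit"))
  if (!identical(fit_small$spec$fixed, fit_large$spec$fixed)) {
    stop_data("REML likelihoods are only comparable for identical mean ",
              "structures")
  }
  if (fit_small$spec$random != "intercept" ||
      fit_large$spec$random != "intercept_slope") {
    stop_data("expected intercept-only vs intercept+slope fits")
  }
  T_ <- max(0, 2 * (fit_large$logLik - fit_small$logLik))
  p <- 0.5 * pchisq(T_, df = 1, lower.tail = FALSE) +
    0.5 * pchisq(T_, df = 2, lower.tail = FALSE)
  list(statistic = T_, p = p)
}

# Moore-Penrose pseudo-inverse (small symmetric matrices).
pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Empirical Bayes prediction of subject-level random effects
#'
#' Best linear unbiased predictions `b_i = G Z_i' V_i^{-1} (y_i - X_i
#' beta)`.  Each subject's prediction is screened by its Mahalanobis
#' distance with respect to the model covariance of the prediction;
#' subjects beyond the chi-square quantile at `level` are flagged as
#' having an exceptional starting point and/or evolution.  Flags are
#' advisory: nothing is removed here.
#'
#' @param fit An [reml_fit()] result.
#' @param level Chi-square flagging quantile (default 0.99).
#' @return Data frame: subject, one column per random effect, `distance`
#'   (squared Mahalanobis), `outlier` flag.
#' @export
empirical_bayes <- function(fit, level = 0.99) {
  stopifnot(inherits(fit, "lmm_fit"))
  G <- as.matrix(fit$G)
  q <- nrow(G)
  Vs <- fit_v_blocks(fit)
  Phi <- fit$vcov_model
  n_s <- length(fit$design$blocks)
  preds <- matrix(0, n_s, q)
  d2 <- numeric(n_s)
  singular <- FALSE
  for (k in seq_len(n_s)) {
    b <- fit$design$blocks[[k]]
    Vinv <- chol2inv(chol(Vs[[k]]))
    ri <- b$y - as.numeric(b$X %*% fit$beta)
    GZt <- G %*% t(b$Z)
    bi <- GZt %*% Vinv %*% ri
    # Var(b_i hat) = G Z'V^{-1}Z G - G Z'V^{-1}X Phi X'V^{-1}Z G
    ZVX <- t(b$Z) %*% Vinv %*% b$X
    Vb <- GZt %*% Vinv %*% t(GZt) -
      (G %*% ZVX) %*% Phi %*% t(G %*% ZVX)
    Vb <- (Vb + t(Vb)) / 2
    Vbi <- tryCatch(solve(Vb), error = function(e) NULL)
    if (is.null(Vbi) || rcond_sym(Vb) < 1e-12) {
      singular <- TRUE
      Vbi <- pinv(Vb)
    }
    preds[k, ] <- bi
    d2[k] <- as.numeric(t(bi) %*% Vbi %*% bi)
  }
  if (singular) {
    warning("near-singular prediction covariance; Mahalanobis distances ",
            "use a pseudo-inverse")
  }
  out <- data.frame(subject = names(fit$design$blocks),
                    stringsAsFactors = FALSE)
  out$intercept <- preds[, 1L]
  if (q == 2L) out$slope <- preds[, 2L]
  out$distance <- d2
  out$outlier <- d2 > qchisq(level, df = q)
  attr(out, "level") <- level
  out
}

rcond_sym <- function(M) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' Predicted response profiles
#'
#' Population-mean prediction `X beta`, optionally plus the subject's
#' empirical Bayes random-effect contribution `Z b_i` for subjects that
#' were in the fitting data.
#'
#' @param fit An [reml_fit()] result.
#' @param newdata Data frame with `time` and `baseline_age` (and
#'   `subject` when `include_random`); defaults to the fitting data.
#' @param include_random Add the subject-specific deviation?
#' @return Numeric vector of predictions.
#' @export
predict_profile <- function(fit, newdata = NULL, include_random = FALSE) {
  stopifnot(inherits(fit, "lmm_fit"))
  center <- attr(fit$data, "center_age")
  if (is.null(newdata)) {
    df <- fit$data
  } else {
    df <- as.data.frame(newdata)
    if (!"baseline_age" %in% names(df) && "age" %in% names(df)) {
      df$baseline_age <- df$age + center
    }
    stopifnot(all(c("time", "baseline_age") %in% names(df)))
  }
  age <- df$baseline_age - center
  X <- fixed_matrix(fit$spec$fixed, df$time, age)
  pred <- as.numeric(X %*% fit$beta)
  if (include_random) {
    if (!"subject" %in% names(df)) {
      stop_data("include_random requires a subject column")
    }
    eb <- empirical_bayes(fit)
    q <- nrow(as.matrix(fit$G))
    for (i in seq_len(nrow(df))) {
      row <- eb[eb$subject == as.character(df$subject[i]), ]
      if (!nrow(row)) {
        stop_data("subject '", df$subject[i],
                  "' was not in the fitting data")
      }
      zi <- if (q == 2L) c(1, df$time[i]) else 1
      bi <- if (q == 2L) c(row$intercept, row$slope) else row$intercept
      pred[i] <- pred[i] + sum(zi * bi)
    }
  }
  pred
}

#' Semi-variogram of within-subject residuals
#'
#' Diagnostic for serial correlation: for each within-subject pair of
#' ordinary-least-squares residuals, half the squared difference
#' `v = (r_ij - r_ik)^2 / 2` is plotted against the time lag
#' `u = |t_ij - t_ik|`.  A flat cloud at the process variance indicates
#' no serial correlation; a curve rising with `u` towards the process
#' variance reveals it.  The total process variance is estimated from
#' half squared differences of residuals taken across subjects.
#'
#' @param data An [lmm_data()].
#' @param fixed Fixed terms of the mean structure used for the OLS
#'   residuals (default `time + age + time_age`).
#' @param n_bins Number of lag bins for the smoothed curve.
#' @return Object of class `"gait_variogram"`: `pairs` (u, v),
#'   `smoothed` (bin midpoints and means), `process_variance`.
#' @export
semivariogram <- function(data, fixed = c("time", "age", "time_age"),
                          n_bins = 10L) {
  stopifnot(inherits(data, "lmm_data"))
  spec <- lmm_spec(fixed = fixed, random = "intercept", serial = "none")
  design <- build_design(data, spec)
  r <- lm.fit(design$X, design$y)$residuals
  u <- numeric(0)
  v <- numeric(0)
  for (b in design$blocks) {
    n_i <- length(b$idx)
    if (n_i < 2L) next
    ri <- r[b$idx]
    for (j in seq_len(n_i - 1L)) {
      k <- (j + 1L):n_i
      u <- c(u, abs(b$times[k] - b$times[j]))
      v <- c(v, 0.5 * (ri[k] - ri[j])^2)
    }
  }
  if (!length(u)) {
    stop_data("no subject has two or more observations")
  }
  # total process variance from cross-subject residual differences
  cross <- outer(r, r, function(a, b) 0.5 * (a - b)^2)
  diffsub <- outer(data$subject, data$subject, "!=")
  process_variance <- mean(cross[diffsub & upper.tri(cross)])
  breaks <- seq(0, max(u), length.out = n_bins + 1L)
  bin <- cut(u, breaks, include.lowest = TRUE)
  smoothed <- data.frame(
    lag = (head(breaks, -1L) + tail(breaks, -1L)) / 2,
    gamma = as.numeric(tapply(v, bin, mean))
  )
  structure(
    list(pairs = data.frame(u = u, v = v), smoothed = smoothed,
         process_variance = process_variance),
    class = "gait_variogram"
  )
}

#' @export
print.gait_variogram <- function(x, ...) {
  cat("Semi-variogram:", nrow(x$pairs), "within-subject pairs; ",
      "process variance", signif(x$process_variance, 4), "\n")
  print(x$smoothed)
  invisible(x)
}
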