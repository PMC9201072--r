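# Cross-sectional comparison of patient-group baseline sessions against a
# typically-developing reference group: descriptives, Shapiro-Wilk
# normality screen, Mann-Whitney U tests, and stepwise Benjamini-Hochberg
# false-discovery-rate control over the comparison family.

#' Descriptive summary of one variable
#'
#' Mean and standard deviation for (approximately) normal variables,
#' median and quartiles otherwise.  Quartiles use linear interpolation
#' between order statistics (`stats::quantile` type 7).
#'
#' @param values Numeric vector, `NA`s dropped.
#' @param normal Report mean/SD (`TRUE`) or median/Q1-Q3 (`FALSE`)?
#' @return Named list: `n` plus `mean`/`sd` or `median`/`q1`/`q3`.
#' @export
describe <- function(values, normal = FALSE) {
  values <- values[!is.na(values)]
  if (!length(values)) stop_data("cannot describe an empty vector")
  if (normal) {
    list(n = length(values), mean = mean(values), sd = sd(values))
  } else {
    q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
    list(n = length(values), median = q[2L], q1 = q[1L], q3 = q[3L])
  }
}

#' Shapiro-Wilk normality screen
#'
#' @param values Numeric vector with 3 to 5000 non-missing values.
#' @return The Shapiro-Wilk p-value (small p: non-normal).  Constant
#'   vectors are degenerate and raise a data error.
#' @export
normality_screen <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L || length(values) > 5000L) {
    stop_data("Shapiro-Wilk requires 3 to 5000 observations, got ",
              length(values))
  }
  if (diff(range(values)) == 0) {
    stop_data("normality screen is undefined for a constant vector")
  }
  unname(shapiro.test(values)$p.value)
}

#' Mann-Whitney U test
#'
#' Rank-based two-sample test.  `U` is the number of (x, y) pairs with
#' `x > y` plus half the tied pairs (the rank-sum form
#' `W_x - n_x(n_x+1)/2`), so `U(x, y) + U(y, x) = n_x * n_y`.  The
#' two-sided p-value uses exact enumeration when the combined sample size
#' is at most `exact_max` and there are no ties, and the tie-corrected
#' normal approximation otherwise.
#'
#' @param x,y Numeric vectors (non-empty after `NA` removal).
#' @param exact_max Combined-n switchover to the normal approximation.
#' @return List with `U`, `p`, and `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 12L) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    stop_data("both groups must be non-empty for the Mann-Whitney U test")
  }
  r <- rank(c(x, y))
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y)) <= exact_max && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = FALSE)
  )
  stopifnot(isTRUE(all.equal(unname(wt$statistic), U)))
  list(U = unname(U), p = unname(wt$p.value),
       method = if (exact) "exact" else "normal approximation")
}

#' Stepwise Benjamini-Hochberg procedure
#'
#' Step-up FDR control at level `q`: with ordered p-values `p_(1) <= ...
#' <= p_(m)`, reject hypotheses `1..k*` where `k*` is the largest `k` with
#' `p_(k) <= k q / m`.  Adjusted p-values are the usual monotone BH
#' values, clipped to 1 and returned in the input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q False discovery rate (default 0.05).
#' @return List with `adjusted` and logical `reject`, both in input
#'   order.
#' @export
benjamini_hochberg <- function(p, q = 0.05) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop_data("p-values must lie in [0, 1]")
  }
  if (q <= 0 || q >= 1) stop_data("q must lie in (0, 1)")
  m <- length(p)
  adjusted <- p.adjust(p, method = "BH")
  ord <- order(p)
  thresh <- seq_len(m) * q / m
  below <- which(p[ord] <= thresh)
  reject <- rep(FALSE, m)
  if (length(below)) reject[ord[seq_len(max(below))]] <- TRUE
  list(adjusted = adjusted, reject = reject)
}

#' Cross-sectional group comparison of gait features
#'
#' Compares each feature between a patient baseline table and a reference
#' (typically-developing) table: group descriptives, Mann-Whitney U, and
#' stepwise Benjamini-Hochberg correction over the whole comparison
#' family.  Following the design that most gait features are not normally
#' distributed, all features are reported as median (Q1-Q3) and tested
#' nonparametrically by default; `force_nonparametric = FALSE` instead
#' screens each variable with Shapiro-Wilk (pooled per group at
#' `alpha_normal`) and reports mean/SD where both groups pass.
#'
#' @param group1,group2 Feature tables ([session_features()] rows or any
#'   data frame of numeric columns).
#' @param variables Columns to compare; defaults to all shared numeric
#'   columns (use the 31-feature family plus subject characteristics for
#'   the published 36-comparison family).
#' @param q FDR level.
#' @param force_nonparametric Use MWU + median(Q1-Q3) for every variable.
#' @param alpha_normal Shapiro-Wilk screening level.
#' @param labels Optional group labels for printing.
#' @return Data frame of class `"gait_comparison"`, one row per variable.
#' @export
compare_groups <- function(group1, group2, variables = NULL, q = 0.05,
                           force_nonparametric = TRUE,
                           alpha_normal = 0.05,
                           labels = c("group1", "group2")) {
  if (is.null(variables)) {
    num1 <- names(group1)[vapply(group1, is.numeric, TRUE)]
    num2 <- names(group2)[vapply(group2, is.numeric, TRUE)]
    variables <- intersect(num1, num2)
  }
  if (!length(variables)) stop_data("no variables to compare")
  rows <- lapply(variables, function(v) {
    x <- group1[[v]]
    y <- group2[[v]]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    normal <- FALSE
    if (!force_nonparametric && length(x) >= 3 && length(y) >= 3 &&
        diff(range(x)) > 0 && diff(range(y)) > 0) {
      normal <- normality_screen(x) > alpha_normal &&
        normality_screen(y) > alpha_normal
    }
    d1 <- describe(x, normal = normal)
    d2 <- describe(y, normal = normal)
    mw <- mann_whitney_u(x, y)
    data.frame(
      variable = v, normal = normal,
      n1 = d1$n, n2 = d2$n,
      loc1 = if (normal) d1$mean else d1$median,
      lo1 = if (normal) d1$mean - d1$sd else d1$q1,
      hi1 = if (normal) d1$mean + d1$sd else d1$q3,
      loc2 = if (normal) d2$mean else d2$median,
      lo2 = if (normal) d2$mean - d2$sd else d2$q1,
      hi2 = if (normal) d2$mean + d2$sd else d2$q3,
      U = mw$U, p = mw$p, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  bh <- benjamini_hochberg(out$p, q = q)
  out$p_adjusted <- bh$adjusted
  out$significant <- bh$reject
  attr(out, "q") <- q
  attr(out, "labels") <- labels
  class(out) <- c("gait_comparison", class(out))
  out
}

#' @export
print.gait_comparison <- function(x, digits = 4, ...) {
  labs <- attr(x, "labels")
  cat("Cross-sectional comparison (", labs[1L], " vs ", labs[2L],
      "), FDR q = ", attr(x, "q"), "\n\n", sep = "")
  fmt <- function(loc, lo, hi) {
    sprintf("%.*g (%.*g to %.*g)", digits, loc, digits, lo, digits, hi)
  }
  tab <- data.frame(
    variable = x$variable,
    g1 = fmt(x$loc1, x$lo1, x$hi1),
    g2 = fmt(x$loc2, x$lo2, x$hi2),
    p_adj = sprintf("%.4f%s", x$p_adjusted,
                    ifelse(x$significant, "*", "")),
    stringsAsFactors = FALSE
  )
  names(tab) <- c("variable", labs[1L], labs[2L], "BH p")
  print(tab, row.names = FALSE, right = FALSE)
  invisible(x)
}
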