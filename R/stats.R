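# Clinical statistics layer: two-group comparisons, correlation, linear
# regression with standardized coefficients, stepwise selection and
# Bland-Altman agreement. Sign convention throughout: group 1 is the
# normal-control group, statistics are group1 minus group2, so signs match
# the usual NC-versus-patient table layout.

new_two_group_test <- function(statistic_name, statistic, p_value, n1, n2,
                               extra = list()) {
  structure(c(list(statistic_name = statistic_name, statistic = statistic,
                   p_value = p_value, n1 = n1, n2 = n2), extra),
            class = "two_group_test")
}

#' @export
print.two_group_test <- function(x, ...) {
  cat(sprintf("Two-group test (%s): statistic = %.4f, p = %.4g (n1 = %d, n2 = %d)\n",
              x$statistic_name, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' Student's t with the pooled variance estimate, computed directly from the
#' printed group means and SDs: `t = (mean1 - mean2) / (sp * sqrt(1/n1 + 1/n2))`
#' with `sp^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)`,
#' `df = n1 + n2 - 2`, two-sided p.
#'
#' @param n1,mean1,sd1 size, mean and SD of group 1 (convention: NC).
#' @param n2,mean2,sd2 size, mean and SD of group 2.
#' @return a `two_group_test` with `statistic_name = "t"` and `df`.
#' @examples
#' t_from_summary(50, 46.88, 10.60, 50, 50.20, 9.73)  # t = -1.632
#' @export
t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2 || n2 < 2) stop("validation error: each group needs n >= 2", call. = FALSE)
  if (!is.finite(sd1) || !is.finite(sd2) || sd1 <= 0 || sd2 <= 0) {
    stop("validation error: group SDs must be positive", call. = FALSE)
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- (mean1 - mean2) / se
  p <- 2 * stats::pt(-abs(tval), df)
  new_two_group_test("t", tval, p, n1, n2,
                     extra = list(df = df, mean1 = mean1, mean2 = mean2))
}

#' Pooled-variance two-sample t-test from raw samples
#'
#' Equivalent to [t_from_summary()] applied to the samples' own moments.
#'
#' @param x1,x2 numeric samples (group 1 = NC convention).
#' @return a `two_group_test`.
#' @export
t_from_raw <- function(x1, x2) {
  x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]
  if (length(x1) < 2 || length(x2) < 2) {
    stop("validation error: each sample needs at least 2 finite values", call. = FALSE)
  }
  s1 <- stats::sd(x1); s2 <- stats::sd(x2)
  if (s1 == 0 && s2 == 0 && mean(x1) == mean(x2)) {
    return(new_two_group_test("t", 0, 1, length(x1), length(x2),
                              extra = list(df = length(x1) + length(x2) - 2,
                                           mean1 = mean(x1), mean2 = mean(x2))))
  }
  t_from_summary(length(x1), mean(x1), s1, length(x2), mean(x2), s2)
}

#' Mann-Whitney U test with normal approximation
#'
#' The U statistic counts pairs where a group-1 value exceeds a group-2 value
#' (ties counted 1/2). The Z value uses the normal approximation with the
#' tie-corrected variance and a 0.5 continuity correction toward the null
#' mean, so a smaller group-1 distribution gives negative Z (NC-first table
#' convention). Two-sided p from Z, or from the exact permutation
#' distribution when `exact = TRUE` (tie-free samples, n1, n2 <= 10).
#'
#' @param x1,x2 numeric samples (group 1 = NC convention).
#' @param exact use the exact U distribution for the p-value (no ties only).
#' @return a `two_group_test` with `statistic_name = "Z"` and element `U`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$U  # 0
#' @export
mann_whitney <- function(x1, x2, exact = FALSE) {
  x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 1 || n2 < 1) stop("validation error: both samples must be non-empty", call. = FALSE)
  r <- rank(c(x1, x2))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nn <- n1 + n2
  ties <- table(c(x1, x2))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term / (nn * (nn - 1)))
  if (sigma2 <= 0 || u1 == mu) {
    z <- 0
  } else {
    cc <- 0.5 * sign(mu - u1)  # continuity correction toward the null mean
    z <- (u1 - mu + cc) / sqrt(sigma2)
  }
  if (exact) {
    if (n1 > 10 || n2 > 10) stop("exact mode supports n1, n2 <= 10", call. = FALSE)
    if (tie_term > 0) stop("exact mode requires tie-free samples", call. = FALSE)
    p <- stats::pwilcox(min(u1, n1 * n2 - u1), n1, n2)
    p <- min(1, 2 * p)
  } else {
    p <- if (z == 0) 1 else 2 * stats::pnorm(-abs(z))
  }
  new_two_group_test("Z", z, p, n1, n2, extra = list(U = u1))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction:
#' `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, df = 1.
#'
#' @param a,b count row 1 (e.g. group-1 positives, group-1 negatives... lay
#'   the table out as groups x categories: `a`,`b` = group 1, `c`,`d` = group 2).
#' @param c,d count row 2.
#' @return a `two_group_test` with `statistic_name = "chi2"`.
#' @examples
#' chi_square_2x2(29, 21, 26, 24)$statistic  # 0.364 (3 d.p.)
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
    stop("validation error: counts must be non-negative integers", call. = FALSE)
  }
  if (any(c(a + b, c + d, a + c, b + d) == 0)) {
    stop("validation error: all table margins must be positive", call. = FALSE)
  }
  n <- a + b + c + d
  chi2 <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  new_two_group_test("chi2", chi2, p, a + b, c + d, extra = list(df = 1))
}

#' Pearson product-moment correlation
#'
#' @param x,y equal-length samples (n >= 3) with non-zero variance.
#' @return list with `r`, `p_value` (t-based, df = n - 2) and `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("validation error: at least 3 paired values required", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("validation error: degenerate variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Linear regression with standardized coefficients
#'
#' Ordinary least squares of `y` on the columns of `X`, reporting the
#' standardized coefficient per predictor, `beta_std = b * sd(x) / sd(y)`,
#' two-sided coefficient p-values, R-squared and adjusted R-squared. In a
#' univariable fit the standardized coefficient equals the Pearson
#' correlation.
#'
#' @param y numeric outcome.
#' @param X data.frame or matrix of predictors (full column rank required).
#' @return an object of class `regression_result` with `predictors`,
#'   `beta_std`, `beta_raw`, `p_values`, `r_squared`, `adj_r_squared`, `n`.
#' @export
ols_standardized <- function(y, X) {
  X <- as.data.frame(X)
  ok <- is.finite(y) & Reduce(`&`, lapply(X, is.finite))
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y); p <- ncol(X)
  if (n <= p + 1) stop("validation error: n must exceed number of predictors + 1", call. = FALSE)
  mm <- cbind(`(Intercept)` = 1, as.matrix(X))
  if (qr(mm)$rank < ncol(mm)) {
    stop("collinearity error: predictors are rank deficient", call. = FALSE)
  }
  fit <- stats::lm(y ~ ., data = X)
  sm <- summary(fit)
  co <- sm$coefficients[-1, , drop = FALSE]
  sdx <- vapply(X, stats::sd, numeric(1))
  sdy <- stats::sd(y)
  structure(list(predictors = colnames(X),
                 beta_raw = unname(co[, 1]),
                 beta_std = unname(co[, 1] * sdx / sdy),
                 p_values = unname(co[, 4]),
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Linear model (n = %d): R^2 = %.3f, adj. R^2 = %.3f\n",
              x$n, x$r_squared, x$adj_r_squared))
  if (length(x$predictors) == 0) {
    cat("  (empty model)\n")
  } else {
    for (i in seq_along(x$predictors)) {
      cat(sprintf("  %-16s beta_std = %+.3f  p = %.4g\n",
                  x$predictors[i], x$beta_std[i], x$p_values[i]))
    }
  }
  invisible(x)
}

#' Stepwise linear regression by p-value entry/removal
#'
#' Iterative forward entry (add the candidate with the smallest coefficient
#' p-value if below `p_enter`) followed by backward removal (drop the model
#' term with the largest p-value if above `p_remove`), repeated until stable.
#' Deterministic: ties are broken by candidate order.
#'
#' @param y numeric outcome.
#' @param X data.frame of candidate predictors.
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.10, must be `>= p_enter`).
#' @return a `regression_result` restricted to the selected predictors; if no
#'   candidate enters, an empty model with `r_squared = 0` and
#'   `selected_none = TRUE`.
#' @export
stepwise_select <- function(y, X, p_enter = 0.05, p_remove = 0.10) {
  X <- as.data.frame(X)
  if (p_enter > p_remove) stop("validation error: p_enter must be <= p_remove", call. = FALSE)
  ok <- is.finite(y) & Reduce(`&`, lapply(X, is.finite))
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  selected <- character(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 2L * ncol(X) + 10L) break  # guard against entry/removal cycling
    changed <- FALSE
    # forward step
    candidates <- setdiff(colnames(X), selected)
    if (length(candidates) > 0) {
      pvals <- vapply(candidates, function(cand) {
        fit <- ols_standardized(y, X[, c(selected, cand), drop = FALSE])
        fit$p_values[match(cand, fit$predictors)]
      }, numeric(1))
      best <- which.min(pvals)
      if (pvals[best] < p_enter) {
        selected <- c(selected, candidates[best])
        changed <- TRUE
      }
    }
    # backward step
    if (length(selected) > 0) {
      fit <- ols_standardized(y, X[, selected, drop = FALSE])
      worst <- which.max(fit$p_values)
      if (fit$p_values[worst] > p_remove) {
        selected <- setdiff(selected, fit$predictors[worst])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(selected) == 0) {
    return(structure(list(predictors = character(0), beta_raw = numeric(0),
                          beta_std = numeric(0), p_values = numeric(0),
                          r_squared = 0, adj_r_squared = 0, n = length(y),
                          selected_none = TRUE),
                     class = "regression_result"))
  }
  out <- ols_standardized(y, X[, selected, drop = FALSE])
  out$selected_none <- FALSE
  out
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = m2 - m1`; bias is `mean(d)` and the 95% limits of
#' agreement are `bias +/- 1.96 sd(d)`.
#'
#' @param m1,m2 equal-length paired measurements.
#' @return an object of class `agreement_result` with `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, `n`.
#' @examples
#' bland_altman(c(36, 37), c(39, 41))
#' @export
bland_altman <- function(m1, m2) {
  if (length(m1) != length(m2)) stop("validation error: paired samples must have equal length", call. = FALSE)
  ok <- is.finite(m1) & is.finite(m2)
  m1 <- m1[ok]; m2 <- m2[ok]
  if (length(m1) < 2) stop("validation error: at least 2 pairs required", call. = FALSE)
  d <- m2 - m1
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 sd_diff = s, n = length(d)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f, 95%% LOA [%.3f, %.3f]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}
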