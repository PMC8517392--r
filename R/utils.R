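# Internal numerics and RNG plumbing shared across modules.

# Trapezoidal quadrature on an arbitrary strictly increasing grid.
trapz <- function(x, y) {
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

#' Differentiate a sampled signal
#'
#' Central differences at interior points and three-point second-order
#' one-sided differences at the two endpoints (exact for quadratics).
#' Works on non-uniform grids.
#'
#' @param t strictly increasing sample times.
#' @param y sample values, same length as `t`.
#' @return numeric vector of derivative estimates on the same grid.
#' @keywords internal
#' @noRd
central_diff <- function(t, y) {
  n <- length(y)
  if (n < 3) stop("insufficient data: at least 3 samples required", call. = FALSE)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d[1] <- onesided3(t[1], t[1:3], y[1:3])
  d[n] <- onesided3(t[n], t[(n - 2):n], y[(n - 2):n])
  d
}

# Derivative of the quadratic through (x, y) evaluated at x0 (Lagrange form).
onesided3 <- function(x0, x, y) {
  y[1] * (2 * x0 - x[2] - x[3]) / ((x[1] - x[2]) * (x[1] - x[3])) +
    y[2] * (2 * x0 - x[1] - x[3]) / ((x[2] - x[1]) * (x[2] - x[3])) +
    y[3] * (2 * x0 - x[1] - x[2]) / ((x[3] - x[1]) * (x[3] - x[2]))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards; keeps sampling order-independent.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stable 31-bit string hash (polynomial rolling, prime modulus) used to derive
# per-subject RNG substreams from the master seed and the subject id, so that
# generation is reproducible independently of subject order.
stable_seed <- function(...) {
  s <- paste(unlist(list(...)), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# Truncated normal draws by resampling; bounds are physiologic guards well in
# the tails, so rejection is cheap.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  guard <- 0L
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncation bounds incompatible with distribution", call. = FALSE)
  }
  x
}

# Log-normal parameters matched to a printed median and interquartile range.
lnorm_from_median_iqr <- function(median, iqr) {
  if (median <= 0 || iqr <= 0) stop("median and IQR must be positive", call. = FALSE)
  # Q3 - Q1 = 2 * median * sinh(z75 * sdlog), z75 = qnorm(0.75)
  z75 <- stats::qnorm(0.75)
  sdlog <- asinh(iqr / (2 * median)) / z75
  list(meanlog = log(median), sdlog = sdlog)
}

# Mean and sd of a log-normal truncated to [0, upper], by numerical integration.
lnorm_trunc_moments <- function(meanlog, sdlog, upper) {
  mass <- stats::plnorm(upper, meanlog, sdlog)
  m1 <- stats::integrate(function(x) x * stats::dlnorm(x, meanlog, sdlog),
                         0, upper, rel.tol = 1e-10)$value / mass
  m2 <- stats::integrate(function(x) x^2 * stats::dlnorm(x, meanlog, sdlog),
                         0, upper, rel.tol = 1e-10)$value / mass
  list(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

rlnorm_trunc <- function(n, meanlog, sdlog, upper) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  bad <- which(x > upper)
  while (length(bad) > 0L) {
    x[bad] <- stats::rlnorm(length(bad), meanlog, sdlog)
    bad <- bad[x[bad] > upper]
  }
  x
}
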