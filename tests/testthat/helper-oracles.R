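# Independent oracles used to cross-check the package implementations.
# They deliberately use different algorithms from the code under test.

# Least squares by explicitly formed normal equations.
ols_normal_equations <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Non-negative least squares by exhaustive enumeration of active sets with
# a KKT optimality check (feasible only for small numbers of columns).
nnls_enumerate <- function(X, y, tol = 1e-9) {
  p <- ncol(X)
  best <- NULL
  for (size in 0:p) {
    for (subset in combn_list(p, size)) {
      x <- numeric(p)
      if (size > 0) {
        coef <- tryCatch(ols_normal_equations(X[, subset, drop = FALSE], y),
                         error = function(e) NULL)
        if (is.null(coef) || any(coef < -tol)) next
        x[subset] <- pmax(coef, 0)
      }
      grad <- drop(t(X) %*% (y - X %*% x))
      # KKT: gradient <= 0 on the zero set, ~0 on the active set
      zero_ok <- all(grad[x <= tol] <= tol * max(1, max(abs(grad))))
      act_ok <- size == 0 || all(abs(grad[subset]) <= 1e-6 * max(1, sum(abs(y))))
      if (zero_ok && act_ok) {
        rss <- sum((y - X %*% x)^2)
        if (is.null(best) || rss < best$rss - tol) best <- list(x = x, rss = rss)
      }
    }
  }
  best$x
}

combn_list <- function(n, k) {
  if (k == 0) return(list(integer(0)))
  m <- utils::combn(n, k)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

# Closed-form single-sinusoid fit by regression on sin and cos regressors:
# x = a sin(wt) + b cos(wt) + m -> amplitude sqrt(a^2+b^2),
# phase atan2(b, a) (degrees in [0, 360)).
sincos_fit <- function(x, period) {
  t <- seq_along(x) - 1
  w <- 2 * pi / period
  X <- cbind(1, sin(w * t), cos(w * t))
  beta <- ols_normal_equations(X, x)
  amp <- sqrt(beta[2]^2 + beta[3]^2)
  phase <- (atan2(beta[3], beta[2]) * 180 / pi) %% 360
  list(amplitude = amp, phase_deg = phase, offset = beta[1],
       rss = sum((x - X %*% beta)^2))
}

# Direct-summation raw autocorrelation (simple loop, no vectorized tricks).
autocorr_loop <- function(x, lag) {
  total <- 0
  for (t in seq_len(length(x) - lag)) total <- total + x[t] * x[t + lag]
  total
}

circular_diff_deg <- function(a, b) {
  abs(((a - b + 180) %% 360) - 180)
}

small_grid <- function(n = 36, period_samples = 12) {
  time_grid(seq(0, by = 25, length.out = n),
            period_minutes = 25 * period_samples)
}
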